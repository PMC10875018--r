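# Chemokine signaling panel (editable default; one HGNC symbol per line)
CCL2
CCL3
CCL4
CCL5
CCL8
CCL11
CCL17
CCL19
CCL20
CCL21
CCL22
CXCL1
CXCL2
CXCL5
CXCL8
CXCL9
CXCL10
CXCL11
CXCL12
CXCL13
CXCL14
CXCL16
CX3CL1
XCL1
CCR1
CCR2
CCR4
CCR5
CCR7
CXCR3
CXCR4
CXCR5
CXCR6
CX3CR1
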