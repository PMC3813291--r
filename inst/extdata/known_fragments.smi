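# identifiable fragment structures from the reference descriptor table
c1ccccc1	3BRA
c1ccc2ncccc2c1	2OHL
c1ccc2cnccc2c1	2OHK
c1ccc2[nH]cnc2c1	3MSJ
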