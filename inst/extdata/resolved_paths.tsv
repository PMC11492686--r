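species	molecule	path	topology
C_carlesii	M1	contig1-LR11-contig5-contig3-LR10-contig6-contig4-LR9-contig7-LR10-contig2-LR9-contig8-LR11-contig12	linear
Ca_henryi	chr1	contig1-LR7-contig5-LR7	circular
Ca_henryi	chr2	contig4-LR9-contig6-LR9-contig2-LR8	circular
Ca_henryi	chr3	contig3-LR8	circular
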