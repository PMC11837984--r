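backbone_id	modset	charge	ms1_area
H3 27-40	K27un;K36un	2	327166.226212827
H3 27-40	K27me1;K36un	2	304029.8775048849
H3 27-40	K27me2;K36un	2	183091.70050911512
H3 27-40	K27me3;K36un	2	175000.97310820693
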