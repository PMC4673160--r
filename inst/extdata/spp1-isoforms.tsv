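isoform_id	exons
OPNa	1,2,3,5,6,7,8
OPNb	1,2,3,5,7,8
OPNc	1,2,3,6,7,8
OPN4	1,2,3,7,8
OPN5	1,2,3,4,5,6,7,8
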