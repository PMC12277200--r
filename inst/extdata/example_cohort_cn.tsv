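sample_id	gene	copy_number
EX001	CYP2D6	2
EX002	CYP2D6	2
EX003	CYP2D6	1
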