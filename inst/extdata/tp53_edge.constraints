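target_node	target_value	conditioning	a	direction	slack_lo	slack_hi
ATM	0	Wip1=1	1	>=	0	0.999999999
Mdm2	1	ATM=0;Wip1=1	1	>=	0	0.999999999
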