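# Experimental designs of the deposited osmotic-stress smFISH series.
# total_stacks: 331
experiment	condition	replicate	timepoints_min	n_stacks
Exp1_rep1	0.2 M NaCl step	1	0,1,2,4,6,8,10,15,20,25,30,35,40,45,50,55	63
Exp1_rep2	0.2 M NaCl step	2	0,1,2,4,6,8,10,15,20,25,30,35,40,45,50,55	64
Exp2_rep1	0.4 M NaCl step	1	0,1,2,4,6,8,10,15,20,25,30,35,40,45,50,55	72
Exp2_rep2	0.4 M NaCl step	2	0,1,2,4,6,8,10,15,20,25,30,35,40,45,50,55,60	71
Exp2_rep3	0.4 M NaCl step	3	0,2,4,6,8,10,15,20,25,30,35,40,45,50,55	67
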