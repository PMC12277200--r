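sample_id	drug	actionable	category
EX001	citalopram_escitalopram	FALSE	NA
EX001	sertraline	FALSE	S
EX001	paroxetine	FALSE	NA
EX001	fluvoxamine	FALSE	NA
EX001	venlafaxine	FALSE	NA
EX001	vortioxetine	FALSE	NA
EX001	amitriptyline	FALSE	S
EX001	aripiprazole	FALSE	NA
EX001	brexpiprazole	FALSE	NA
EX001	haloperidol	FALSE	NA
EX001	risperidone	FALSE	NA
EX001	pimozide	FALSE	NA
EX001	zuclopenthixol	FALSE	NA
EX001	quetiapine	FALSE	NA
EX002	citalopram_escitalopram	TRUE	NA
EX002	sertraline	FALSE	A
EX002	paroxetine	TRUE	NA
EX002	fluvoxamine	TRUE	NA
EX002	venlafaxine	TRUE	NA
EX002	vortioxetine	TRUE	NA
EX002	amitriptyline	TRUE	A
EX002	aripiprazole	TRUE	NA
EX002	brexpiprazole	TRUE	NA
EX002	haloperidol	TRUE	NA
EX002	risperidone	TRUE	NA
EX002	pimozide	TRUE	NA
EX002	zuclopenthixol	TRUE	NA
EX002	quetiapine	FALSE	NA
EX003	citalopram_escitalopram	FALSE	NA
EX003	sertraline	TRUE	E
EX003	paroxetine	FALSE	NA
EX003	fluvoxamine	FALSE	NA
EX003	venlafaxine	FALSE	NA
EX003	vortioxetine	FALSE	NA
EX003	amitriptyline	TRUE	E
EX003	aripiprazole	FALSE	NA
EX003	brexpiprazole	FALSE	NA
EX003	haloperidol	FALSE	NA
EX003	risperidone	FALSE	NA
EX003	pimozide	TRUE	NA
EX003	zuclopenthixol	TRUE	NA
EX003	quetiapine	FALSE	NA
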