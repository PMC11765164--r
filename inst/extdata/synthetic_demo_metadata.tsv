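sample_id	tissue	status
brain_h001	brain	0
brain_h002	brain	0
brain_h003	brain	0
brain_h004	brain	0
brain_h005	brain	0
brain_h006	brain	0
brain_d001	brain	1
brain_d002	brain	1
brain_d003	brain	1
brain_d004	brain	1
brain_d005	brain	1
brain_d006	brain	1
kidney_h001	kidney	0
kidney_h002	kidney	0
kidney_h003	kidney	0
kidney_h004	kidney	0
kidney_h005	kidney	0
kidney_h006	kidney	0
kidney_d001	kidney	1
kidney_d002	kidney	1
kidney_d003	kidney	1
kidney_d004	kidney	1
kidney_d005	kidney	1
kidney_d006	kidney	1
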