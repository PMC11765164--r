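site_id	category	tissue	healthy_mean	disease_mean
cg00000001	tissue_and_disease	brain	0.616761520002037	0.416761520002037
cg00000004	tissue_and_disease	kidney	0.928011000351980	0.728011000351980
cg00000008	tissue_and_disease	brain	0.578561456429306	0.378561456429306
cg00000009	tissue_and_disease	kidney	0.777981678568758	0.977981678568758
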