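gene	condition	replicate	ct_target	ct_reference
FIXTURE	treated	1	20.000	20.000
FIXTURE	treated	2	20.000	20.000
FIXTURE	treated	3	20.000	20.000
FIXTURE	control	1	25.6187	20.000
FIXTURE	control	2	25.6187	20.000
FIXTURE	control	3	25.6187	20.000
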