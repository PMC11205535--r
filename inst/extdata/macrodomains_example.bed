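U00096	400000	1200000	Right
U00096	1200000	2000000	Ter
U00096	2000000	2800000	Left
U00096	2800000	3400000	NS-left
U00096	3400000	4200000	Ori
U00096	4200000	4640000	NS-right
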