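variable	group	n	cases
sex	Male	116698	11292
sex	Female	113134	18855
age	39-49 years	51191	7201
age	50-59 years	73641	10548
age	60-73 years	105000	12398
vitd_category	<25	21688	3209
vitd_category	>=25 and <50	82389	10548
vitd_category	>=50 and <75	72843	9206
vitd_category	>75	25493	3312
overall	All	202413	26270
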