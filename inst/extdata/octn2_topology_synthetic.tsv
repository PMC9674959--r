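name	class	start	end
N-term	N-term	1	45
TM1	TM	46	66
EL1	EL	67	136
TM2	TM	137	157
IL1	IL	158	167
TM3	TM	168	188
EL2	EL	189	192
TM4	TM	193	213
IL2	IL	214	225
TM5	TM	226	246
EL3	EL	247	255
TM6	TM	256	276
IL3	IL	277	338
TM7	TM	339	359
EL4	EL	360	369
TM8	TM	370	390
IL4	IL	391	401
TM9	TM	402	422
EL5	EL	423	425
TM10	TM	426	446
IL5	IL	447	460
TM11	TM	461	481
EL6	EL	482	493
TM12	TM	494	514
C-term	C-term	515	557
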