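phosphate	strand	promoter
2	template	U6
3	non_template	U6
4	template	U6
5	non_template	U6
7	non_template	U6
8	template	U6
10	template	U6
11	non_template	U6
12	template	U6
13	non_template	U6
14	template	U6
17	non_template	U6
19	non_template	U6
22	template	U6
24	template	U6
25	non_template	U6
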