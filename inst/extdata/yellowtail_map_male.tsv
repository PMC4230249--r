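group	n_markers	n_framework	length_cM
Squ1	34	15	49.28
Squ2	48	18	43.45
Squ3	29	18	54.97
Squ4	25	3	5.57
Squ5	39	17	50.24
Squ6	23	11	42.62
Squ7	32	11	40.41
Squ8	23	12	51.60
Squ9	36	10	52.89
Squ10	36	7	28.60
Squ11	11	6	59.19
Squ12	27	10	52.09
Squ13	25	10	42.63
Squ14	33	11	45.39
Squ15	36	11	55.44
Squ16	27	14	51.66
Squ17	22	7	44.55
Squ18	33	13	57.00
Squ19	26	14	58.45
Squ20	24	10	40.38
Squ21	3	2	1.11
Squ21'	25	5	7.78
Squ22	26	11	54.03
Squ23	26	10	44.03
Squ24	29	11	17.79
Squ24'	4	4	6.68
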