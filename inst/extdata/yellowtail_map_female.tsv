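group	n_markers	n_framework	length_cM
Squ1	33	11	48.19
Squ2	49	14	49.27
Squ3	29	10	40.17
Squ4	28	9	42.82
Squ5	38	9	59.51
Squ6	30	5	50.31
Squ7	29	14	50.66
Squ8	26	8	54.83
Squ9	37	10	30.22
Squ10	35	7	40.60
Squ11	10	1	0.00
Squ12	26	12	26.74
Squ13	26	10	48.03
Squ14	34	9	56.36
Squ15	35	14	37.23
Squ16	25	8	36.12
Squ17	20	10	40.32
Squ18	37	10	45.12
Squ19	30	9	40.52
Squ20	22	9	51.21
Squ21	29	12	44.90
Squ22	26	12	45.87
Squ23	25	7	41.67
Squ24	4	4	15.67
Squ24'	32	8	30.31
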