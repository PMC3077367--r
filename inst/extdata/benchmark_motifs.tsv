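tf	motif_id	length	total_ic	avg_ic
NRSF	V$NRSF_Q4	19	13.58	0.71
c-Fos	MA0099.2	7	5.65	0.81
c-Jun	MA0099.2	7	5.65	0.81
c-Myc	V$MYC_Q2	7	6.90	0.99
Max	MA0058.1	10	7.55	0.75
GATA1	MA0036.1	5	4.65	0.93
YY1	V$YY1_01	17	5.17	0.30
E2F4	V$E2F_Q2	6	4.78	0.80
NFKB	MA0105.1	11	9.50	0.86
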