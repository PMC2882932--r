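protein_id	residue_index	value
T1	1	0.29999999999999999
T1	2	0.29999999999999999
T1	3	0.80000000000000004
T1	4	0.80000000000000004
T1	5	0.80000000000000004
T1	6	0.80000000000000004
T1	7	0.29999999999999999
T1	8	0.29999999999999999
T1	9	0.29999999999999999
T1	10	0.29999999999999999
T1	11	0.29999999999999999
T1	12	0.29999999999999999
T2	1	0.29999999999999999
T2	2	0.29999999999999999
T2	3	0.80000000000000004
T2	4	0.80000000000000004
T2	5	0.80000000000000004
T2	6	0.80000000000000004
T2	7	0.29999999999999999
T2	8	0.29999999999999999
T2	9	0.29999999999999999
T2	10	0.29999999999999999
T2	11	0.29999999999999999
T2	12	0.29999999999999999
T3	1	0.29999999999999999
T3	2	0.29999999999999999
T3	3	0.29999999999999999
T3	4	0.29999999999999999
T3	5	0.29999999999999999
T3	6	0.29999999999999999
T3	7	0.29999999999999999
T3	8	0.29999999999999999
T3	9	0.29999999999999999
T3	10	0.29999999999999999
T3	11	0.29999999999999999
T3	12	0.29999999999999999
T4	1	0.29999999999999999
T4	2	0.29999999999999999
T4	3	0.29999999999999999
T4	4	0.29999999999999999
T4	5	0.29999999999999999
T4	6	0.29999999999999999
T4	7	0.29999999999999999
T4	8	0.29999999999999999
T4	9	0.29999999999999999
T4	10	0.29999999999999999
T4	11	0.29999999999999999
T4	12	0.29999999999999999
T5	1	0.29999999999999999
T5	2	0.29999999999999999
T5	3	0.80000000000000004
T5	4	0.80000000000000004
T5	5	0.80000000000000004
T5	6	0.80000000000000004
T5	7	0.29999999999999999
T5	8	0.29999999999999999
T5	9	0.29999999999999999
T5	10	0.29999999999999999
T5	11	0.29999999999999999
T5	12	0.29999999999999999
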