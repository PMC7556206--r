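r_fast_ripple	patient_id	true_group	predicted_group	correct
0.61	2	1	1	Yes
0.60	12	1	1	Yes
0.36	13	3	1	No
0.34	1	1	1	Yes
0.27	10	2	1	No
0.25	3	2	2	Yes
0.20	5	2	2	Yes
0.15	15	2	2	Yes
0.14	4	1	2	No
0.05	8	1	2	No
0.02	7	2	2	Yes
0.02	16	2	2	Yes
0.01	9	3	3	Yes
0.01	14	3	3	Yes
-0.05	6	2	3	No
-0.05	11	3	3	Yes
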