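patient_id	age	disease_duration	edss
MS1	44	13	0.0
MS2	45	18	2.0
MS3	63	38	5.5
MS4	30	8	3.5
MS5	39	9	1.5
MS6	31	6	1.5
MS7	32	6	2.0
MS8	41	3	0.0
MS9	29	1.5	4.0
MS10	21	0.5	1.5
MS11	37	2	1.5
MS12	39	5	2.5
MS13	37	12	1.5
MS14	44	2	1.0
MS15	37	6	2.5
MS16	25	0.8	1.5
MS17	29	15	3.5
MS18	30	0.5	1.0
MS19	52	19	1.5
MS20	28	1	1.5
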