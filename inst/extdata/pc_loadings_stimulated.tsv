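accession	gene_symbol	pc1	pc2
Q13588	GRAP	0.224	-0.070
Q9H2F5	EPC1	0.213	-0.095
Q6ICL3	TANGO2	0.156	-0.257
Q9BV20	MRI1	0.198	-0.122
Q6UW02	CYP20A1	0.143	-0.210
Q8WV92	MITD1	0.145	-0.313
Q9H4A6	GOLPH3	0.229	-0.028
Q9NWS0	PIH1D1	0.148	-0.299
Q9Y5B6	PAXBP1	-0.137	-0.013
Q96G46	DUS3L	0.186	-0.202
Q9BRQ6	CHCHD6	0.174	-0.091
Q7L8W6	DPH6	-0.183	-0.173
Q8WUK0	PTPMT1	-0.142	-0.184
Q02539	H1-1	0.164	-0.114
Q2TBE0	CWF19L2	-0.164	-0.218
Q5T4S7	UBR4	-0.137	-0.224
P54098	POLG	0.162	-0.307
Q9H2K8	TAOK3	-0.174	-0.192
P17706	PTPN2	-0.204	0.026
Q5THJ4	VPS13D	-0.147	-0.155
Q8IV53	DENND1C	-0.143	-0.044
O94762	RECQL5	-0.157	-0.132
Q2M296	MTHFSD	-0.186	-0.191
Q96SB8	SMC6	-0.144	-0.226
Q8NEM7	SUPT20H	-0.168	0.051
Q8WXA9	SREK1	-0.202	-0.174
Q8IWV7	UBR1	-0.196	-0.009
Q9HC21	SLC25A19	0.152	-0.278
Q5PSV4	BRMS1L	-0.177	-0.118
Q6WCQ1	MPRIP	-0.160	-0.184
Q9BQ69	MACROD1	-0.182	0.015
Q9H410	DSN1	-0.176	-0.154
Q9BYC9	MRPL20	-0.210	-0.070
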