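accession	gene_symbol	pc1	pc2
Q7L8W6	DPH6	-0.253	0.067
Q8TDQ7	GNPDA2	0.156	0.384
Q9UKU7	ACAD8	0.174	0.331
Q92828	CORO2A	0.192	0.366
A8MW92	PHF20L1	-0.261	0.146
Q9HD15	SRA1	-0.255	0.133
Q9H2F5	EPC1	-0.292	0.081
Q12923	PTPN13	-0.245	0.297
Q8TCE6	DENND10	-0.263	0.108
O43504	LAMTOR5	-0.228	0.256
Q9H7Z3	NRDE2	-0.256	-0.045
Q16401	PSMD5	-0.243	0.135
Q9HD26	GOPC	0.162	0.385
Q12797	ASPH	-0.238	0.254
O75764	TCEA3	0.226	0.302
P08134	RHOC	0.249	-0.100
P29597	TYK2	0.194	0.238
Q96GS4	BORCS6	-0.294	-0.046
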