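# Curated cross-species MAPT region homology survey (protein level).
# identity_pct: percent identity of the region against the human reference
# isoforms (776 aa with exon 4a; 833 aa with exon 4a-L), global alignment.
# size_aa: region length in the named species record; NA where not recorded.
# record_note distinguishes multiple records analyzed for one species.
clade	species	record_note	region	identity_pct	size_aa
primates	human	776aa	full	100	776
primates	human	833aa	full	100	833
primates	human	776aa	exon4a	100	251
primates	human	833aa	exon4aL	100	355
primates	chimp	.	exon4a	99	251
primates	gorilla	.	exon4a	98	251
primates	gibbon	.	exon4a	94	NA
primates	baboon	.	exon4a	90	251
primates	lemur	.	exon4a	64	251
primates	chimp	.	exon4aL	98	355
primates	gorilla	.	exon4aL	98	353
primates	baboon	.	exon4aL	90	355
primates	marmoset	.	exon4aL	81	355
mammals	cat	.	full	84	778
mammals	cat	.	Nterm_1_4	86	NA
mammals	cat	.	exon4a	70	248
mammals	cat	.	MTBD_9_13	98	NA
mammals	elephant	.	full	75	760
mammals	elephant	.	Nterm_1_4	83	NA
mammals	elephant	.	exon4a	65	264
mammals	elephant	.	MTBD_9_13	99	NA
mammals	dog	.	full	75	869
mammals	dog	.	Nterm_1_4	87	NA
mammals	dog	.	exon4aL	64	362
mammals	dog	.	MTBD_9_13	99	NA
mammals	rat	.	full	71	750
mammals	rat	.	Nterm_1_4	83	NA
mammals	rat	.	exon4a	56	254
mammals	rat	.	MTBD_9_13	97	NA
mammals	mouse	.	full	72	749
mammals	mouse	.	Nterm_1_4	83	NA
mammals	mouse	.	exon4a	56	253
mammals	mouse	.	MTBD_9_13	97	NA
mammals	opossum	.	full	46	860
mammals	opossum	.	Nterm_1_4	65	NA
mammals	opossum	.	exon4aL	39	347
mammals	opossum	.	MTBD_9_13	94	NA
vertebrates	zebra_finch	.	full	52	705
vertebrates	zebra_finch	.	Nterm_1_4	60	NA
vertebrates	zebra_finch	.	exon4a	24	280
vertebrates	zebra_finch	.	MTBD_9_13	91	NA
vertebrates	eagle	.	full	52	836
vertebrates	eagle	.	Nterm_1_4	62	NA
vertebrates	eagle	.	exon4a	26	305
vertebrates	eagle	.	MTBD_9_13	93	NA
vertebrates	turtle	.	full	52	828
vertebrates	turtle	.	Nterm_1_4	62	NA
vertebrates	turtle	.	exon4aL	28	353
vertebrates	turtle	.	MTBD_9_13	92	NA
vertebrates	crocodile	.	full	50	889
vertebrates	crocodile	.	Nterm_1_4	62	NA
vertebrates	crocodile	.	exon4aL	25	364
vertebrates	crocodile	.	MTBD_9_13	92	NA
vertebrates	frog	.	full	43	745
vertebrates	frog	.	Nterm_1_4	38	NA
vertebrates	frog	.	exon4a	16	226
vertebrates	frog	.	MTBD_9_13	80	NA
vertebrates	toad	.	full	41	760
vertebrates	toad	.	Nterm_1_4	32	NA
vertebrates	toad	.	exon4a	15	262
vertebrates	toad	.	MTBD_9_13	81	NA
vertebrates	salmon	.	full	30	731
vertebrates	salmon	.	Nterm_1_4	20	NA
vertebrates	salmon	.	exon4a	17	320
vertebrates	salmon	.	MTBD_9_13	55	NA
vertebrates	carp	687aa	full	27	687
vertebrates	carp	687aa	Nterm_1_4	16	NA
vertebrates	carp	687aa	exon4a	15	208
vertebrates	carp	687aa	MTBD_9_13	53	NA
vertebrates	carp	814aa	full	34	814
vertebrates	carp	814aa	Nterm_1_4	16	NA
vertebrates	carp	814aa	exon4aL	18	400
vertebrates	carp	814aa	MTBD_9_13	53	NA
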