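id	block_id	domain_tag	order_index	lineage_tag	variant_of	pattern	key_residues	note
M-I	M-I	MocF	1		 	G[TD]E!xxxG!xxx[DN]TxN!	2:E:E11	canonical; highly conserved in all lineages; wall of the molybdopterin pocket
M-II	M-II	MocF	2		 	VGD!NxxxH	2:D:D44	canonical; D44 (3KBQ numbering) is the only residue strictly conserved across all lineages
M-III	M-III	MocF	3		 	G!G!L!G!P!T!xD!D!xT	8:D:D75	canonical; GGTG-like motif shared with MogA/gephyrin; D75 near pyrophosphate site
M-IV	M-IV	MocF	4		 	Nx[KR]QA	2:KR:K114	canonical; weakly conserved outside the archaeal lineage
M-IV(1.3)	M-IV	MocF	4	1.3	M-IV	R!xK!M!A!xxP!	2:K:K114;3:M:M115	archaeal fingerprint variant; K114/M115 face the substrate surface
M-V	M-V	MocF	5		 	N!xxG!xA!PG!	 	canonical; wall opposite M-I in the binding pocket
M-VI	M-VI	MocF	6		 	P!G![VP]P!xE![ML]	0:P:P148;1:G:G149	canonical; PG pair involved in phosphate/ribose binding
M-VII	M-VII	MocF	7		 	PxL	 	canonical; short block marking the end of the MocF domain
i-I	i-I	interdomain	1		 	GhGE!S	 	canonical interdomain block
i-I(1.3)	i-I	interdomain	1	1.3	i-I	GhGE!SxhA!P!	 	archaeal form carrying the conserved xhAP suffix
i-II	i-II	interdomain	2		 	EVxh[RK]h	 	canonical; conserved in all lineages except 1.3
P-I	P-I	CinA	1		 	A!E!S!CTGG!	2:S:S31	canonical; bottom of the active-site pocket; S31 contacts the NMN amide
P-I(2.2.1.2)	P-I	CinA	1	2.2.1.2	P-I	E[QA][CG][ST][GA]G	1:QA:S31-site	inactive two-domain variant; S31-homologous position degenerate
P-I(2.2.3.4)	P-I	CinA	1	2.2.3.4	P-I	SEAACGG	2:A:S31-site	fungal variant; alanine at the S31-homologous position
P-II	P-II	CinA	2		 	G![AS]S	0:G:G46;2:S:S48	canonical; G46/S48 form one wall of the cavity
P-II(2.2.2.2)	P-II	CinA	2	2.2.2.2	P-II	D!T!P!	 	inactive single-domain replacement block
P-II(2.2.1.2)	P-II	CinA	2	2.2.1.2	P-II	A![DP][EQ]	 	inactive two-domain replacement block
P-III	P-III	CinA	3		 	Y!xNxxK!	0:Y:Y58;2:N:N60;5:K:K63	canonical; Y58 and K63 strictly required for deamidase activity
P-III(2.2.2.2)	P-III	CinA	3	2.2.2.2	P-III	F!xD!xxK!	0:F:Y58F;2:D:N60D	probe for the documented Y58F+N60D inactivating substitutions
P-III(2.2.3.4)	P-III	CinA	3	2.2.3.4	P-III	YS[ML]K[TQ]R	0:Y:Y58	fungal fingerprint; tyrosine kept, lysine lost
P-IV	P-IV	CinA	4		 	G![AV]VS	 	canonical; outermost part of the surface depression
P-IV(2.2.2.2)	P-IV	CinA	4	2.2.2.2	P-IV	[ST]AVS	 	YdeJ-homolog variant
P-IV(2.2.1.2)	P-IV	CinA	4	2.2.1.2	P-IV	[GE]x[VL][SA]	 	YfaY-homolog variant
P-IV(2.2.3.4)	P-IV	CinA	4	2.2.3.4	P-IV	MGPS	 	fungal variant
P-V	P-V	CinA	5		 	M!AxG!x	 	canonical; structural block, absent from inactive two-domain enzymes
P-VI	P-VI	CinA	6		 	[ST]G[IV]A!G!P!xG!G!	0:ST:ST105;1:G:G106	canonical; most conserved CinA block; S/T105-G106 contact the NMN amino group
P-VI(2.2.1.2)	P-VI	CinA	6	2.2.1.2	P-VI	[SV]xxxxx[EH]	 	degenerate YfaY-homolog form
P-VI(2.2.2.2)	P-VI	CinA	6	2.2.2.2	P-VI	[ST]GYGGP	 	YdeJ-homolog form
P-VII	P-VII	CinA	7		 	KPVG!TV	3:G:G120	canonical; G120 near the binding pocket; block deleted in inactive two-domain enzymes
P-VIII	P-VIII	CinA	8		 	Rxx[VI]R	0:R:R145	canonical; R145 closes the pocket and may bind the phosphate group
P-IX	P-IX	CinA	9		 	L!xxL!xxxL!	 	canonical; leucine repeat of the long C-terminal helix, shared by all lineages
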