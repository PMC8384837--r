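repeat_id	base	trm	wildtype
1	A	IFV	FALSE
1	C	QFR	FALSE
1	G	SGD	FALSE
1	U	NYQ	FALSE
2	A	VFQ	FALSE
2	C	---	FALSE
2	G	---	FALSE
2	U	NWP	FALSE
3	A	PHQ	FALSE
3	C	QFR	FALSE
3	G	THE	FALSE
3	U	NYQ	FALSE
4	A	SRQ	FALSE
4	C	TFR	FALSE
4	G	---	FALSE
4	U	---	FALSE
5	A	PHQ	FALSE
5	C	---	FALSE
5	G	SWD	FALSE
5	U	RAN	FALSE
6	A	VFQ	FALSE
6	C	---	FALSE
6	G	SWD	FALSE
6	U	NYQ	TRUE
7	A	PHQ	FALSE
7	C	---	FALSE
7	G	SNE	TRUE
7	U	NPG	FALSE
8	A	CFP	FALSE
8	C	---	FALSE
8	G	---	FALSE
8	U	NYQ	TRUE
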