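protein_a	domain_a	protein_b	domain_b	exons_a	exons_b	transcripts_a	transcripts_b	direction
EGFR	PF07714	GRB2	PF00017	ENSE00001001;ENSE00001002	ENSE00002001	ENST00000275493	ENST00000316615	ab
GRB2	PF00018	SOS1	PF00617	ENSE00002002	ENSE00003001	ENST00000316615	ENST00000402219	ab
SOS1	PF00617	STAT3	PF00704	ENSE00003001	ENSE00004001	ENST00000402219	ENST00000264657	ab
EGFR	PF07714	STAT3	PF01017	ENSE00001001;ENSE00001002	ENSE00004002	ENST00000275493	ENST00000264657	
GRB2	PF00017	STAT3	PF01017	ENSE00002001	ENSE00004002	ENST00000316615	ENST00000264657	
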