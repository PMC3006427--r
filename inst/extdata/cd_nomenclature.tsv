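label	parent	variants	negatives	status
mt-MRCA		.	.	placeholder
C	mt-MRCA	.	.	placeholder
C1	C	.	.	placeholder
C1a	C1	.	.	placeholder
C4	C	.	.	placeholder
C4a'b'c	C4	2232.1A	.	defined
C4a	C4a'b'c	.	.	placeholder
C4a1	C4a	.	.	placeholder
C4a1a	C4a1	.	.	placeholder
C4a1a1	C4a1a	.	.	placeholder
C4a1a2	C4a1a	.	.	placeholder
C4a1a2b	C4a1a2	.	.	placeholder
C4b	C4a'b'c	.	.	placeholder
C4b2	C4b	.	.	placeholder
C4b4	C4b	.	.	placeholder
C4b5	C4b	.	.	placeholder
C4b6	C4b	.	.	placeholder
C4b7	C4b	.	.	placeholder
C4b8	C4b	.	.	placeholder
C4c	C4a'b'c	.	.	placeholder
C4e	C4	151,152,7307,15479	2232.1A	defined
C5	C	.	.	placeholder
C5a	C5	.	.	placeholder
C5a2	C5a	.	.	placeholder
C5a2a	C5a2	.	.	placeholder
C5a2a1	C5a2a	.	.	placeholder
C5b	C5	.	.	placeholder
C5b1	C5b	.	.	placeholder
C5b1a	C5b1	.	.	placeholder
C5c	C5	10454,16093,16518T,16527	.	defined
C5c1	C5c	16234	.	defined
C5c1a	C5c1	7694	.	defined
C5c2	C5c	16291	.	defined
C5d	C5	.	.	placeholder
C7	C	.	.	placeholder
C7a	C7	.	.	placeholder
C7a1	C7a	.	.	placeholder
C7a1a	C7a1	.	.	placeholder
D	mt-MRCA	.	.	placeholder
D2	D	.	.	placeholder
D4	D	.	.	placeholder
D4b	D4	.	.	placeholder
D4b1	D4b	.	.	placeholder
D4b1a	D4b1	.	.	placeholder
D4b1a2	D4b1a	.	.	placeholder
D4b1a2a	D4b1a2	.	.	placeholder
D4b1a2a1	D4b1a2a	16173,16223,16319,16362	.	defined
D4b1a2a1a	D4b1a2a1	16093	.	defined
D4b1a2a1b	D4b1a2a1	16129	.	defined
D4b1a2a2	D4b1a2a	.	.	placeholder
D4e	D4	.	.	placeholder
D4e4	D4e	.	.	placeholder
D4e4a	D4e4	.	.	placeholder
D4e4b	D4e4	.	.	placeholder
D4j	D4	.	.	placeholder
D4j4	D4j	.	.	placeholder
D4j5	D4j	.	.	placeholder
D4j7	D4j	.	.	placeholder
D4j8	D4j	.	.	placeholder
D4j9	D4j	.	.	placeholder
D4j10	D4j	.	.	placeholder
D4l	D4	.	.	placeholder
D4l2	D4l	.	.	placeholder
D4m	D4	.	.	placeholder
D4m2	D4m	.	.	placeholder
D4m2a	D4m2	.	.	placeholder
D5	D	.	.	placeholder
D5a	D5	.	.	placeholder
D5a3	D5a	16360	.	defined
D5a3a	D5a3	16126,16136	.	defined
D6	D	.	.	placeholder
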