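dimer_complex	dimer_model	blocker_complex	blocker_model	interface	overlap_stated	blocks_reported
CXCR2-CXCR2	AF-3	CXCR2-Iso_2TM	CP-16	TM4/TM5	TRUE	TRUE
CXCR2-CXCR2	AF-3	CXCR2-Iso_4TM	CP-28	TM4/TM5	TRUE	TRUE
CXCR2-CXCR1	CP-H18	CXCR2-Iso_2TM	CP-17	TM6/TM7	TRUE	TRUE
CXCR2-CXCR1	CP-H18	CXCR2-Iso_3TM	CP-10	TM6/TM7	TRUE	TRUE
CXCR2-CXCR1	CP-H18	CXCR2-Iso_4TM	AF-5	TM6/TM7	TRUE	TRUE
CXCR7-CXCR7	CP-H8	CXCR7-Iso_4TM	CP-H14	NA	FALSE	FALSE
CCR2-CCR2	CP-11	CCR2-Iso_2TM	CP-13	TM1/TM2	TRUE	TRUE
CCR2-CCR5	CP-11	CCR2-Iso_2TM	CP-13	TM1/TM2	TRUE	TRUE
CCR2-CXCR4	AF-2	CCR2-Iso_2TM	CP-18	TM6/TM7	TRUE	TRUE
CCR7-CCR7	AF-2	CCR7-Iso_5TM	CP-H18	TM1/TM7/TM2	TRUE	TRUE
CCR7-CXCR4	AF-2	CCR7-Iso_5TM	CP-H18	TM1/TM7/TM2	TRUE	TRUE
CCR7-CXCR4	AF-4	CCR7-Iso_5TM	CP-H18	TM1/TM7/TM2	TRUE	TRUE
CCR7-CXCR4	CP-19	CCR7-Iso_5TM	CP-H10	TM3/TM4/TM5	TRUE	TRUE
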