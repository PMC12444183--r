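# Illustrative lipid-metabolic and inflammatory gene sets (example members
# only; NOT the curated pathway snapshots used in any published analysis).
FAS	illustrative fatty acid synthesis	ACACA	ACACB	FASN	ACLY	ELOVL6	SCD	ACSS2	MCAT	OLAH
FAE	illustrative fatty acid elongation	ELOVL1	ELOVL2	ELOVL3	ELOVL4	ELOVL5	ELOVL7	HACD1	HACD2	TECR	HSD17B12
FAD	illustrative fatty acid degradation	CPT1A	CPT1B	CPT2	ACADM	ACADL	ACADS	ACADVL	HADHA	HADHB	ECI1	ACOX1	ACAA1	ACAA2	ECHS1	ACAT1
Chol	illustrative cholesterol synthesis	HMGCR	HMGCS1	MVK	PMVK	MVD	IDI1	FDPS	FDFT1	SQLE	LSS	DHCR7	DHCR24	CYP51A1	SC5D
Inflammatory	illustrative inflammatory panel	IL6	TNF	IL1B	CXCL8	CCL2	PTGS2	NFKB1	STAT1	IFNG	IL10
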