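mirna_id	gene_id	votes
hsa-let-7b	ASPA	3
hsa-miR-130a	ABAT	3
hsa-miR-130b	ESR1	3
hsa-miR-136	CXCL14	3
hsa-miR-148a	FAM134B	3
hsa-miR-148b	SORD	3
hsa-miR-152	ABAT	3
hsa-miR-181c	ESR1	3
hsa-miR-181d	FAM134B	3
hsa-miR-182	SORD	3
hsa-miR-18a	ABAT	3
hsa-miR-18b	ESR1	3
hsa-miR-19a	FAM134B	3
hsa-miR-206	IGF1	3
hsa-miR-22	SORD	3
hsa-miR-221	ABAT	3
hsa-miR-222	ESR1	3
hsa-miR-26b	PBLD	3
hsa-miR-29a	PCK1	3
hsa-miR-29c	ASPA	3
hsa-miR-302a	FAM134B	3
hsa-miR-302b	CXCL14	3
hsa-miR-302c	SORD	3
hsa-miR-302d	ABAT	3
hsa-miR-31	ESR1	3
hsa-miR-340	IGF1	3
hsa-miR-372	FAM134B	3
hsa-miR-373	PBLD	3
hsa-miR-410	PCK1	3
hsa-miR-425	ASPA	3
hsa-miR-488	CXCL14	3
hsa-miR-495	IGF1	3
hsa-miR-506	SORD	3
hsa-miR-520b	PBLD	3
hsa-miR-520e	PCK1	3
hsa-miR-93	ABAT	3
hsa-miR-96	ESR1	3
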