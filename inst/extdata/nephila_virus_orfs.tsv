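virus	orf	start	end	aa_reported	consistent
NcPV1	polyprotein	761	10147	3128	TRUE
NcPV2	ORF1	722	7226	2412	FALSE
NcPV2	ORF2	7948	9747	599	TRUE
NcPV2	ORF3	9792	10562	256	TRUE
NcPV2	ORF4	10702	11457	251	TRUE
NcPV3	polyprotein	680	8914	2744	TRUE
NcVV1	ORF1	9	6809	2266	TRUE
NcVV2	ORF2	8934	11051	705	TRUE
NcBV	L	56	7285	2409	TRUE
NcRV1	RNA1	10	4005	1331	TRUE
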