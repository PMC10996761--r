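patient_id	virtual_seizure_free	radius_virtual_mm	radius_actual_mm	soz_rr	rons_rr	fr_rr	spatial_frnet	temporal_frnet_a	temporal_frnet_b	percent_r	novel_r
IO005	TRUE	29.85	22.40	0.818	0.821	0.776	0.000	2.222	0.207	0.600	0.800
IO012	FALSE	NA	18.42	1.000	0.879	0.737	3.083	4.898	0.084	0.818	0.471
469	TRUE	53.05	33.44	1.000	0.824	0.947	0.000	1.249	0.353	0.857	0.478
4110	TRUE	35.08	27.11	0.318	0.191	0.833	0.000	1.282	0.088	0.162	0.905
462	TRUE	75.66	26.06	1.000	0.906	0.429	4.360	0.894	0.262	1.000	0.600
IO023	TRUE	74.12	9.02	1.000	0.935	0.942	0.000	1.206	0.096	0.000	1.000
IO013	FALSE	NA	85.60	1.000	0.769	0.814	2.517	1.076	1.000	1.000	0.832
IO015	FALSE	NA	50.24	0.625	0.992	0.915	3.261	1.629	0.099	0.000	1.000
IO019	FALSE	NA	64.90	1.000	0.998	0.932	2.602	1.001	1.000	1.000	0.589
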