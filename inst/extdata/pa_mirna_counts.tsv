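set	family	mirna	pa2	pa4	fc_printed	pvalue_printed	star_pa2	star_pa4
conserved	MIR169	pas-miR169a-3p	252	142	-0.83	2.27E-08	180	87
conserved	MIR169	pas-miR169b-3p	244	0	-11.16	2.77E-74	173	0
conserved	MIR169	pas-miR169c-3p	244	0	-11.16	2.77E-74	173	0
conserved	MIR169	pas-miR169d	18	26	0.53	2.35E-01	0	0
conserved	MIR169	pas-miR169e	18	26	0.53	2.35E-01	0	0
conserved	MIR159	pas-miR159-3p	117706	141387	0.26	0	115	83
conserved	MIR159	pas-miR319a-3p	1312	85	-3.95	0	16	0
conserved	MIR408	pas-miR408a-3p	1475	6263	2.08	0	50	208
conserved	MIR408	pas-miR408b-3p	1475	6263	2.08	0	50	208
conserved	MIR396	pas-miR396a	7879	6831	-0.21	1.86E-18	142	153
conserved	MIR396	pas-miR396b	2808	3441	0.29	2.11E-15	120	263
conserved	MIR396	pas-miR396c-3p	0	30	8.13	9.61E-10	13	11
conserved	MIR396	pas-miR396d-3p	0	30	8.13	9.61E-10	13	11
conserved	MIR397	pas-miR397a	676	6543	3.27	0	16	368
conserved	MIR397	pas-miR397b	678	6601	3.28	0	16	368
conserved	MIR398	pas-miR398a-3p	532	3071	2.53	0	44	1042
conserved	MIR398	pas-miR398b-3p	532	3071	2.53	0	44	1042
conserved	MIR398	pas-miR398c-3p	532	3071	2.53	0	44	1042
conserved	MIR166	pas-miR166a-3p	178621	189900	0.09	3.20E-72	1809	1883
conserved	MIR166	pas-miR166b-3p	180817	192950	0.09	1.90E-82	141	332
conserved	MIR166	pas-miR166c-3p	550961	563946	0.03	2.62E-29	1689	1755
conserved	MIR166	pas-miR166d-3p	422623	424471	0.00	2.78E-01	373	236
conserved	MIR166	pas-miR166e-3p	50932	51265	0.01	4.71E-01	490	455
conserved	MIR160	pas-miR160a	718	1445	1.01	8.76E-56	0	1
conserved	MIR160	pas-miR160b	30	40	0.41	2.38E-01	0	0
conserved	MIR160	pas-miR160c	30	40	0.41	2.38E-01	0	0
conserved	MIR160	pas-miR160d	30	40	0.41	2.38E-01	0	0
conserved	MIR160	pas-miR160e	30	40	0.41	2.38E-01	0	0
conserved	MIR160	pas-miR160f	30	40	0.41	2.38E-01	0	0
conserved	MIR156	pas-miR156a	2251	3231	0.51	5.59E-39	0	0
conserved	MIR156	pas-miR156b	2251	3221	0.51	4.75E-39	46	69
conserved	MIR156	pas-miR156c	1349	2284	0.76	1.94E-54	278	493
conserved	MIR156	pas-miR156d	1349	2284	0.76	1.94E-54	278	493
conserved	MIR164	pas-miR164	396	284	-0.48	1.51E-05	85	40
conserved	MIR167	pas-miR167	509	864	0.76	8.46E-22	18	27
conserved	MIR168	pas-miR168a	1893	2713	0.52	2.06E-33	143	236
conserved	MIR168	pas-miR168b	1895	2712	0.51	3.58E-33	137	185
conserved	MIR2118	pas-miR2118a-3p	109	136	0.32	8.78E-02	0	0
conserved	MIR2118	pas-miR2118b-3p	109	136	0.32	8.78E-02	0	0
conserved	MIR482	pas-miR482a-3p	4727	6806	0.52	5.00E-83	0	0
conserved	MIR482	pas-miR482b-3p	4529	4723	0.06	5.48E-02	0	0
conserved	MIR482	pas-miR482c-3p	4728	6804	0.52	8.48E-83	0	0
conserved	MIR171	pas-miR171a	0	10	6.54	9.87E-04	0	0
conserved	MIR171	pas-miR171b	0	8	6.22	3.94E-03	0	0
conserved	MIR171	pas-miR171c	0	8	6.22	3.94E-03	0	0
novel	NA	pas-mir1	116	422	1.86	7.02E-42	106	74
novel	NA	pas-mir2	43	0	-8.65	1.09E-13	0	0
novel	NA	pas-mir3	8	3	-1.42	1.45E-01	6	5
novel	NA	pas-mir4a	6	0	-5.81	1.55E-02	0	0
novel	NA	pas-mir4b	6	0	-5.81	1.55E-02	0	0
novel	NA	pas-mir5a	7116	6078	-0.23	5.38E-20	208	223
novel	NA	pas-mir5b	7116	6078	-0.23	5.38E-20	208	223
novel	NA	pas-mir6a-3p	2125	4098	0.94	1.51E-139	67	71
novel	NA	pas-mir6b-3p	2125	4098	0.94	1.51E-139	67	71
novel	NA	pas-mir6c-3p	2125	4098	0.94	1.51E-139	67	71
novel	NA	pas-mir7-3p	696	0	-12.67	1.51E-210	6	0
novel	NA	pas-mir8a-3p	29	0	-8.08	4.57E-01	0	0
novel	NA	pas-mir8b-3p	29	11	-1.4	5.48E-02	0	0
novel	NA	pas-mir9	8	0	-6.23	3.87E-03	0	0
novel	NA	pas-mir10-3p	10	0	-6.55	9.66E-04	0	0
novel	NA	pas-mir11-3p	17	0	-7.31	7.49E-06	0	0
novel	NA	pas-mir12	5	0	-5.55	3.11E-02	0	0
novel	NA	pas-mir13-3p	934	1506	0.69	5.10E-31	1128	1403
novel	NA	pas-mir14	10	28	1.48	3.45E-03	2	1
novel	NA	pas-mir15a	345	0	-11.66	9.86E-105	107	0
novel	NA	pas-mir16a-3p	0	19	7.47	1.95E-06	0	0
novel	NA	pas-mir16b-3p	0	19	7.47	1.95E-06	0	0
novel	NA	pas-mir16c-3p	0	19	7.47	1.95E-06	0	0
novel	NA	pas-mir17-3p	0	8	6.22	3.94E-03	0	7
novel	NA	pas-mir18-3p	0	11	6.68	4.94E-04	0	0
novel	NA	pas-mir19-3p	0	126	10.2	1.34E-38	0	0
novel	NA	pas-mir20-3p	0	54	8.98	5.87E-17	0	2
novel	NA	pas-mir21a	0	12	6.81	2.47E-04	0	9
novel	NA	pas-mir21b	0	12	6.81	2.47E-04	0	9
novel	NA	pas-mir22-3p	0	11	6.68	4.94E-04	0	0
novel	NA	pas-mir23-3p	0	28	8.03	3.84E-09	0	0
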