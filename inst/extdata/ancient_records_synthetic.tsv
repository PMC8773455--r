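record_id	haplogroup	date_ce	longitude	latitude	site
anc_H5a1_band	H5a1	-480	102	47	band_site_H5a1
anc_H5a1_west	H5a1	-700	72	45	west_site_H5a1
anc_J1b2_band	J1b2	-450	100	47	band_site_J1b2
anc_J1b2_west	J1b2	-800	68	45	west_site_J1b2
anc_U2e1b_band	U2e1b	-500	108	47	band_site_U2e1b
anc_U2e1b_west	U2e1b	-650	75	45	west_site_U2e1b
anc_U4b1a1a1_band	U4b1a1a1	-520	95	47	band_site_U4b1a1a1
anc_U4b1a1a1_west	U4b1a1a1	-900	62	45	west_site_U4b1a1a1
anc_U4b1a4_band	U4b1a4	-400	110	47	band_site_U4b1a4
anc_U4b1a4_west	U4b1a4	-600	78	45	west_site_U4b1a4
anc_T2g_band	T2g1a	-430	104	47	band_site_T2g
anc_T2g_west	T2g	-750	73	45	west_site_T2g
anc_I1c_band	I1c	-300	101	47	band_site_I1c
anc_I1c_west	I1c	-1200	46	45	west_site_I1c
anc_J1b1b1_band	J1b1b1	400	103	47	band_site_J1b1b1
anc_J1b1b1_west	J1b1b1	-300	48	45	west_site_J1b1b1
anc_J1d6_band	J1d6	-200	97	47	band_site_J1d6
anc_U2e1a1_band	U2e1a1	300	105	47	band_site_U2e1a1
anc_U2e1a1_west	U2e1a1	-100	50	45	west_site_U2e1a1
anc_U4d2_band	U4d2	-350	99	47	band_site_U4d2
anc_U4d2_west	U4d2	-1100	44	45	west_site_U4d2
anc_U5b1c2_band	U5b1c2	-250	106	47	band_site_U5b1c2
anc_U8b1a1_band	U8b1a1	-480	92	47	band_site_U8b1a1
anc_U8b1a1_west	U8b1a1	-1500	30	45	west_site_U8b1a1
anc_U5a1_band	U5a1	-3000	101	47	band_site_U5a1
anc_U5a1_west	U5a1	-3500	60	45	west_site_U5a1
anc_H1b_band	H1b	-1500	90	47	band_site_H1b
anc_H1c_band	H1c	-1800	93	47	band_site_H1c
anc_H1j_band	H1j	-1300	96	47	band_site_H1j
anc_K1_band	K1	-2500	100	47	band_site_K1
anc_T1a_band	T1a	-1600	94	47	band_site_T1a
anc_I4_band	I4	-2000	98	47	band_site_I4
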