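marker_id	chrom	pos	repeat_unit	reference_length
HP01	sim1	2000000	A	12
HP02	sim1	2005000	T	13
HP03	sim1	2010000	A	14
HP04	sim1	2015000	T	15
HP05	sim1	2020000	A	16
HP06	sim1	2025000	T	17
HP07	sim1	2030000	A	18
HP08	sim1	2035000	T	19
HP09	sim1	2040000	A	20
HP10	sim1	2045000	T	12
HP11	sim1	2050000	A	13
HP12	sim1	2055000	T	14
HP13	sim1	2060000	A	15
HP14	sim1	2065000	T	16
HP15	sim1	2070000	A	17
HP16	sim1	2075000	T	18
HP17	sim1	2080000	A	19
HP18	sim1	2085000	T	20
HP19	sim1	2090000	A	12
HP20	sim1	2095000	T	13
HP21	sim1	2100000	A	14
HP22	sim1	2105000	T	15
HP23	sim1	2110000	A	16
HP24	sim1	2115000	T	17
HP25	sim1	2120000	A	18
HP26	sim1	2125000	T	19
HP27	sim1	2130000	A	20
HP28	sim1	2135000	T	12
HP29	sim1	2140000	A	13
HP30	sim1	2145000	T	14
HP31	sim1	2150000	A	15
HP32	sim1	2155000	T	16
HP33	sim1	2160000	A	17
HP34	sim1	2165000	T	18
HP35	sim1	2170000	A	19
HP36	sim1	2175000	T	20
HP37	sim1	2180000	A	12
HP38	sim1	2185000	T	13
HP39	sim1	2190000	A	14
HP40	sim1	2195000	T	15
NR-21	sim1	2200000	A	21
BAT-26	sim1	2205000	A	26
BAT-25	sim1	2210000	T	25
NR-24	sim1	2215000	A	24
MONO-27	sim1	2220000	A	27
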