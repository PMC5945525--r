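sample_id	msi_40	msi_45	promega
17_001	High	High	High
17_002	High	High	High
17_003	High	High	High
17_004	High	High	High
17_005	High	High	High
17_006	High	High	High
17_007	High	High	High
17_008	High	High	High
17_009	High	High	High
17_010	High	High	High
17_011	Stable	Stable	High
17_012	High	High	High
17_013	High	High	High
17_014	High	High	High
17_015	High	High	High
17_016	High	High	High
17_017	High	High	High
17_018	High	High	High
17_019	High	High	High
17_020	High	High	High
17_021	High	High	High
17_022	Stable	Stable	Stable
17_023	Stable	Stable	Stable
17_024	Stable	Stable	Stable
17_025	Stable	Stable	Stable
17_026	Stable	Stable	Stable
17_027	Stable	Stable	Stable
17_028	Stable	Stable	Stable
17_029	Stable	Stable	Stable
17_030	Stable	Stable	Stable
17_031	Stable	Stable	Stable
17_032	High	High	High
17_033	Stable	Stable	Stable
17_034	High	High	High
17_035	High	High	High
17_036	High	High	High
17_037	High	High	High
17_038	High	Stable	Stable
17_039	High	High	High
17_040	High	High	High
17_041	High	High	High
17_042	High	High	High
17_043	High	High	High
17_044	Stable	Stable	Stable
17_045	Stable	Stable	Stable
17_046	High	High	High
17_047	High	High	High
17_048	High	High	High
17_049	High	High	High
17_050	Stable	Stable	Stable
17_051	High	High	High
17_052	High	High	High
17_053	Stable	Stable	Stable
BR14-43 05-01T	Stable	Stable	Stable
BR14-48 05-01T	Stable	Stable	Stable
BR14-13 05-01T	Stable	Stable	Stable
BR14-131 05-01T	Stable	Stable	Stable
BR14-239 05-01T	Stable	Stable	Stable
BR13-102T	Stable	Stable	Stable
BR-14-248_05-02	Stable	Stable	Stable
BR-14-48_05-02T	Stable	Stable	Stable
BR-15-183_05-1	Stable	Stable	Stable
BR-15-57_05-01	Stable	Stable	Stable
BR-14-283_05-01	Stable	Stable	Stable
BR11-49 396-4T	Stable	Stable	Stable
BR11-93 T	Stable	Stable	Stable
BR12-11 1041-3T	Stable	Stable	Stable
BR12-15 T	Stable	Stable	Stable
BR13-162 05-01T	Stable	Stable	Stable
BR13-163 T	Stable	Stable	Stable
BR13-191 05-01T	Stable	Stable	Stable
BR13-184 05-01T	Stable	Stable	Stable
BR13-25 05-01T	Stable	Stable	Stable
BR11-71 T	Stable	Stable	Stable
NP-17963 T	High	High	High
NP-18023 T	High	High	High
NP-18212 T	High	High	High
NP-18215 T	High	High	High
BR14-209 05-01T	High	High	High
BR13-29 05-01T	High	High	High
BR-14-267_05-02	Stable	Stable	High
BR-14-202_05-1	High	High	High
BR-13-170_05-01T	High	High	High
BR-15-12_05-01	High	High	High
BR-14-312_05-01	High	High	High
BR-15-37_05-01	High	High	High
BR12-110 T	High	High	High
BR12-30 T	High	High	High
BR14-88 05-01T	Stable	Stable	Stable
BR14-194 05-01T	Stable	Stable	Stable
BR-14-51_05-01T	Stable	Stable	Stable
BR-15-168_05-01	Stable	Stable	Stable
BR-14-138_05-02T	Stable	Stable	Stable
BR-15-90_05-01	Stable	Stable	Stable
BR-14-253_05-02	Stable	Stable	Stable
BR-14-97_07-01N	Stable	Stable	Stable
BR-13-187_05-02T	Stable	Stable	Stable
BR-14-20_05-01T	Stable	Stable	Stable
BR-14-231_05-03T	Stable	Stable	Stable
BR-14-257_05-03	Stable	Stable	Stable
BR-14-293_05-01	Stable	Stable	Stable
BR-15-23_05-01	Stable	Stable	Stable
BR-15-70 _05-01	Stable	Stable	Stable
BR-12-37 1265_3	Stable	Stable	Stable
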