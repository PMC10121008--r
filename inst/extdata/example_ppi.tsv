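# example PPI edge list, STRING-style integer confidence scores
g0003	g0005	414
g0005	g0006	686
g0001	g0007	839
g0003	g0009	816
g0005	g0009	687
g0006	g0009	917
g0003	g0010	663
g0008	g0010	547
g0006	g0013	442
g0009	g0014	460
g0012	g0015	590
g0002	g0016	711
g0011	g0016	797
g0014	g0016	644
g0006	g0017	948
g0010	g0017	576
g0011	g0017	675
g0005	g0018	599
g0008	g0018	791
g0009	g0018	555
g0009	g0019	687
g0014	g0019	860
g0019	g0020	451
g0014	g0021	925
g0004	g0022	603
g0002	g0024	904
g0011	g0024	608
g0013	g0024	600
g0023	g0024	686
g0007	g0025	935
g0012	g0025	919
g0019	g0025	634
g0012	g0026	866
g0014	g0026	976
g0019	g0026	661
g0022	g0026	828
g0021	g0027	640
g0025	g0027	595
g0009	g0028	854
g0012	g0028	522
g0018	g0028	827
g0022	g0028	473
g0006	g0029	547
g0020	g0029	486
g0022	g0030	544
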