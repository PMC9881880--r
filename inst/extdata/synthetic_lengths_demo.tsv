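gene	length
G0001	2392
G0002	809
G0003	2063
G0004	2105
G0005	868
G0006	1715
G0007	603
G0008	795
G0009	402
G0010	2297
G0011	3407
G0012	3895
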