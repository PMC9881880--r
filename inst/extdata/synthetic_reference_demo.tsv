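from	to
G0001	G0003
G0001	G0004
G0001	G0005
G0001	G0006
G0002	G0006
G0002	G0007
G0002	G0008
G0002	G0010
G0004	G0005
G0005	G0010
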