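gene	S001	S002	S003	S004	S005	S006
G0001	29486	119486	57201	50896	53862	40055
G0002	16908	3190	3341	37652	4351	3161
G0003	764	3763	2807	2470	1605	2413
G0004	2600	7792	12341	20163	3547	4432
G0005	7744	39647	35922	23569	26352	19708
G0006	3343	1487	2488	19075	886	1620
G0007	12002	5026	9544	14701	6670	8759
G0008	12788	2766	5169	50913	3149	6553
G0009	94125	107440	140043	37475	91192	91798
G0010	10465	57484	6537	132770	99668	64384
G0011	5026	7474	17183	13887	20665	34418
G0012	1999	3665	4736	13763	5982	33833
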