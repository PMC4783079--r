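compound_id	S_S	T_T	T_Ekd	T_Edis	E_T	E_Ekd	E_Edis
c1	1.0	1.0	0.23809523809523808	0.3333333333333333	0.23809523809523808	0.6	0.3333333333333333
c2	0.7777777777777778	0.3333333333333333	0.14285714285714285	0.3333333333333333	0.14285714285714285	0.2	0.5
c3	0.7777777777777778	0.3333333333333333	0.23809523809523808	0.3333333333333333	0.14285714285714285	0.09090909090909091	0.2
c4	0.45454545454545453	0.0	0.14285714285714285	0.0	0.0	0.1	0.0
c5	0.0	0.0	0.08333333333333333	0.0	0.0	0.1	0.0
c6	0.3333333333333333	NA	NA	NA	0.14285714285714285	0.045454545454545456	0.2
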