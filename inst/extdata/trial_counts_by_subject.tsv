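subject	trials	movements	thumb	index	middle	ring	little
1	400	409	93	79	80	78	79
2	400	485	87	97	117	97	87
3	300	380	74	59	84	81	82
4	400	435	83	77	86	80	109
5	400	396	68	105	88	71	64
6	400	396	80	79	80	79	78
7	400	394	79	77	80	79	79
8	400	394	80	80	79	75	80
9	400	395	80	80	75	80	80
10	400	394	80	79	80	75	80
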