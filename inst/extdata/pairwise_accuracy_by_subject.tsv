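subject	thumb_vs_index	thumb_vs_middle	thumb_vs_ring	thumb_vs_little	index_vs_middle	index_vs_ring	index_vs_little	middle_vs_ring	middle_vs_little	ring_vs_little
1	68.89	69.82	83.21	93.33	62.97	77.03	94.50	64.23	91.87	91.47
2	67.36	70.62	71.11	63.03	72.74	69.95	78.14	63.14	68.23	71.92
3	75.12	75.73	87.57	76.63	89.74	87.22	80.04	94.91	71.19	90.34
4	66.77	67.61	70.03	82.86	57.53	63.84	92.39	64.67	94.13	86.95
5	63.06	76.40	72.00	78.00	67.37	70.86	76.12	81.87	75.86	70.62
6	56.65	66.72	74.32	95.87	62.00	63.40	95.70	55.16	96.97	97.77
7	71.50	73.65	58.20	75.50	55.13	64.67	57.97	69.26	55.71	72.90
8	56.88	57.48	67.58	59.13	65.13	71.29	58.22	62.03	62.32	67.97
9	99.16	98.77	99.09	94.06	62.61	81.25	83.06	71.97	76.39	70.44
10	87.29	86.56	92.39	63.25	96.29	85.33	80.23	84.23	86.78	81.74
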