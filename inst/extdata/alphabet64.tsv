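# 64-state backbone dihedral alphabet (degrees)
# Derived by k-means (k = 64, torus embedding, seed 20110526) of phi/psi
# pairs harvested from the bio3d example chains 1DPX, 1HEL and HIV-1
# protease. Versioned stand-in for a PDB-wide structural alphabet; the
# table is user-replaceable via load_alphabet(path).
# columns: index phi psi
1	-149.97	153.54
2	-149.19	126.23
3	-138.1	22.53
4	-136.56	67.5
5	-135.54	152.45
6	-130.41	137.46
7	-125.25	2.42
8	-123.97	-14.69
9	-121.96	89.25
10	-115.64	-39.97
11	-112.57	14.66
12	-107.27	-0.16
13	-102.15	166.73
14	-101.97	130.86
15	-101.58	-28.45
16	-95.15	112.87
17	-93.27	-17.97
18	-90.91	-1.74
19	-90.32	5.66
20	-88.6	95.76
21	-85.25	8.52
22	-85.05	143.99
23	-83.01	-21.26
24	-81.46	-44.52
25	-81.28	169.72
26	-79.12	0.47
27	-78.27	78.59
28	-77.15	-10.9
29	-76.46	130.06
30	-71.43	-28.25
31	-70.43	-37.78
32	-70.21	-42.08
33	-68.79	-44.69
34	-67.93	-20.71
35	-67.44	141.58
36	-67.05	-2.31
37	-66.85	155.7
38	-66.31	-14.52
39	-66.25	-45.15
40	-65.51	-42.51
41	-65.31	-36.77
42	-63.74	-46.82
43	-62.97	116.91
44	-62.39	-26.11
45	-62.28	-34.24
46	-61.55	133.22
47	-61.49	-41.55
48	-59.52	-44.33
49	-58.68	-51.47
50	-57.79	-30.37
51	-55.46	130.31
52	-53.89	-36.61
53	-50.61	126.11
54	-47.58	-49.95
55	42.28	61
56	53.05	55.07
57	56.01	36.95
58	58.84	-138.82
59	64.25	23.71
60	69.95	7.29
61	76.2	19.81
62	82.28	-168.77
63	85.85	1.56
64	134.43	-49.32
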