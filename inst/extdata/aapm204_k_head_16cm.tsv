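# Size conversion factors k(d_eff) for the 16-cm head reference phantom
# Source: AAPM Report 204, effective-diameter table; entries computed from the
# report's published exponential fit k = 1.874799 * exp(-0.03871313 * d_eff_cm),
# rounded to the report's 2-decimal table precision.
d_eff_cm	k
8	1.38
9	1.32
10	1.27
11	1.22
12	1.18
13	1.13
14	1.09
15	1.05
16	1.01
17	0.97
18	0.93
19	0.9
20	0.86
21	0.83
22	0.8
23	0.77
24	0.74
25	0.71
26	0.69
27	0.66
28	0.63
29	0.61
30	0.59
31	0.56
32	0.54
33	0.52
34	0.5
35	0.48
36	0.47
37	0.45
38	0.43
39	0.41
40	0.4
41	0.38
42	0.37
43	0.35
44	0.34
45	0.33
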