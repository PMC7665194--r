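index	x_deg	y_deg	blind_spot	gh_sector	in_24_2
1	-9	27	FALSE	none	FALSE
2	-3	27	FALSE	none	FALSE
3	3	27	FALSE	none	FALSE
4	9	27	FALSE	none	FALSE
5	-15	21	FALSE	none	FALSE
6	-9	21	FALSE	IT	TRUE
7	-3	21	FALSE	IT	TRUE
8	3	21	FALSE	IN	TRUE
9	9	21	FALSE	IN	TRUE
10	15	21	FALSE	none	FALSE
11	-21	15	FALSE	none	FALSE
12	-15	15	FALSE	IT	TRUE
13	-9	15	FALSE	IT	TRUE
14	-3	15	FALSE	IT	TRUE
15	3	15	FALSE	IT	TRUE
16	9	15	FALSE	IN	TRUE
17	15	15	FALSE	IN	TRUE
18	21	15	FALSE	none	FALSE
19	-27	9	FALSE	none	FALSE
20	-21	9	FALSE	IT	TRUE
21	-15	9	FALSE	IT	TRUE
22	-9	9	FALSE	T	TRUE
23	-3	9	FALSE	T	TRUE
24	3	9	FALSE	T	TRUE
25	9	9	FALSE	T	TRUE
26	15	9	FALSE	N	TRUE
27	21	9	FALSE	N	TRUE
28	27	9	FALSE	none	FALSE
29	-27	3	FALSE	IT	TRUE
30	-21	3	FALSE	IT	TRUE
31	-15	3	FALSE	IT	TRUE
32	-9	3	FALSE	T	TRUE
33	-3	3	FALSE	T	TRUE
34	3	3	FALSE	T	TRUE
35	9	3	FALSE	T	TRUE
36	15	3	TRUE	none	TRUE
37	21	3	FALSE	N	TRUE
38	27	3	FALSE	none	FALSE
39	-27	-3	FALSE	ST	TRUE
40	-21	-3	FALSE	ST	TRUE
41	-15	-3	FALSE	ST	TRUE
42	-9	-3	FALSE	T	TRUE
43	-3	-3	FALSE	T	TRUE
44	3	-3	FALSE	T	TRUE
45	9	-3	FALSE	T	TRUE
46	15	-3	TRUE	none	TRUE
47	21	-3	FALSE	N	TRUE
48	27	-3	FALSE	none	FALSE
49	-27	-9	FALSE	none	FALSE
50	-21	-9	FALSE	ST	TRUE
51	-15	-9	FALSE	ST	TRUE
52	-9	-9	FALSE	T	TRUE
53	-3	-9	FALSE	T	TRUE
54	3	-9	FALSE	T	TRUE
55	9	-9	FALSE	T	TRUE
56	15	-9	FALSE	N	TRUE
57	21	-9	FALSE	N	TRUE
58	27	-9	FALSE	none	FALSE
59	-21	-15	FALSE	none	FALSE
60	-15	-15	FALSE	ST	TRUE
61	-9	-15	FALSE	ST	TRUE
62	-3	-15	FALSE	ST	TRUE
63	3	-15	FALSE	ST	TRUE
64	9	-15	FALSE	SN	TRUE
65	15	-15	FALSE	SN	TRUE
66	21	-15	FALSE	none	FALSE
67	-15	-21	FALSE	none	FALSE
68	-9	-21	FALSE	ST	TRUE
69	-3	-21	FALSE	ST	TRUE
70	3	-21	FALSE	SN	TRUE
71	9	-21	FALSE	SN	TRUE
72	15	-21	FALSE	none	FALSE
73	-9	-27	FALSE	none	FALSE
74	-3	-27	FALSE	none	FALSE
75	3	-27	FALSE	none	FALSE
76	9	-27	FALSE	none	FALSE
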