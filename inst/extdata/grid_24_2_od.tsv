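index	x_deg	y_deg	blind_spot	gh_sector	in_24_2
1	-9	21	FALSE	IT	TRUE
2	-3	21	FALSE	IT	TRUE
3	3	21	FALSE	IN	TRUE
4	9	21	FALSE	IN	TRUE
5	-15	15	FALSE	IT	TRUE
6	-9	15	FALSE	IT	TRUE
7	-3	15	FALSE	IT	TRUE
8	3	15	FALSE	IT	TRUE
9	9	15	FALSE	IN	TRUE
10	15	15	FALSE	IN	TRUE
11	-21	9	FALSE	IT	TRUE
12	-15	9	FALSE	IT	TRUE
13	-9	9	FALSE	T	TRUE
14	-3	9	FALSE	T	TRUE
15	3	9	FALSE	T	TRUE
16	9	9	FALSE	T	TRUE
17	15	9	FALSE	N	TRUE
18	21	9	FALSE	N	TRUE
19	-27	3	FALSE	IT	TRUE
20	-21	3	FALSE	IT	TRUE
21	-15	3	FALSE	IT	TRUE
22	-9	3	FALSE	T	TRUE
23	-3	3	FALSE	T	TRUE
24	3	3	FALSE	T	TRUE
25	9	3	FALSE	T	TRUE
26	15	3	TRUE	none	TRUE
27	21	3	FALSE	N	TRUE
28	-27	-3	FALSE	ST	TRUE
29	-21	-3	FALSE	ST	TRUE
30	-15	-3	FALSE	ST	TRUE
31	-9	-3	FALSE	T	TRUE
32	-3	-3	FALSE	T	TRUE
33	3	-3	FALSE	T	TRUE
34	9	-3	FALSE	T	TRUE
35	15	-3	TRUE	none	TRUE
36	21	-3	FALSE	N	TRUE
37	-21	-9	FALSE	ST	TRUE
38	-15	-9	FALSE	ST	TRUE
39	-9	-9	FALSE	T	TRUE
40	-3	-9	FALSE	T	TRUE
41	3	-9	FALSE	T	TRUE
42	9	-9	FALSE	T	TRUE
43	15	-9	FALSE	N	TRUE
44	21	-9	FALSE	N	TRUE
45	-15	-15	FALSE	ST	TRUE
46	-9	-15	FALSE	ST	TRUE
47	-3	-15	FALSE	ST	TRUE
48	3	-15	FALSE	ST	TRUE
49	9	-15	FALSE	SN	TRUE
50	15	-15	FALSE	SN	TRUE
51	-9	-21	FALSE	ST	TRUE
52	-3	-21	FALSE	ST	TRUE
53	3	-21	FALSE	SN	TRUE
54	9	-21	FALSE	SN	TRUE
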