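source	target	direction	reliable
a26	a03	A	1
a04	a36	L	1
a42	a52	A	1
a55	a26	A	1
a24	a37	L	1
a33	a13	D	1
a47	a24	L	1
a13	a47	A	1
a45	a55	A	0
a36	a42	A	1
a03	a24	A	1
a53	a33	D	1
a52	a47	D	1
a47	a42	A	0
a42	a03	D	1
a45	a12	A	1
a12	a55	D	1
a37	a53	A	1
a47	a05	D	1
a14	a07	A	1
a03	a45	D	1
a12	a14	D	1
a45	a39	A	1
a61	a39	L	1
a42	a37	D	1
a39	a04	L	0
a45	a33	D	1
a28	a45	D	1
a12	a53	D	1
a53	a36	A	1
a28	a33	D	1
a45	a04	D	1
a04	a52	D	1
a15	a55	D	1
a13	a55	A	0
a55	a12	A	1
a15	a36	A	1
a03	a12	D	1
a47	a61	A	1
a12	a37	D	1
a13	a14	D	1
a61	a37	D	1
a36	a61	L	1
a33	a24	L	1
a52	a36	A	1
a45	a05	A	1
a55	a07	D	1
a53	a39	A	1
a37	a33	L	1
a45	a36	A	1
a13	a45	A	0
a55	a28	L	1
a45	a42	L	1
a55	a37	A	1
a13	a33	A	1
a55	a15	A	1
a61	a04	L	1
a14	a52	A	1
a24	a15	A	1
a36	a47	D	0
a36	a03	D	1
a47	a04	A	1
a37	a47	A	1
a24	a03	A	1
a47	a39	A	1
a26	a07	L	1
a42	a28	D	1
a37	a04	A	1
a12	a47	D	1
a12	a39	A	1
a36	a05	L	0
a61	a36	L	1
a14	a03	D	0
a05	a36	L	1
a05	a03	D	1
a14	a24	A	1
a05	a61	L	1
a12	a36	A	1
a52	a53	D	1
a37	a13	D	1
a07	a12	A	1
a53	a26	D	1
a13	a42	A	1
a24	a53	A	1
a33	a37	L	1
a12	a61	A	1
a05	a15	D	0
a47	a45	D	1
a52	a55	D	1
a42	a05	A	1
a55	a33	D	0
a03	a42	A	1
a03	a39	A	1
a37	a36	A	1
a61	a24	D	1
a03	a04	A	1
a07	a37	D	1
a26	a36	A	1
a39	a14	D	1
a53	a24	D	1
a61	a45	D	0
a55	a52	A	1
a05	a12	D	1
a15	a24	D	1
a04	a53	D	1
a61	a15	D	1
a15	a45	D	1
a26	a45	A	1
a15	a52	A	1
a14	a26	A	1
a37	a07	D	1
a15	a05	A	0
a39	a42	D	0
a37	a03	L	0
a39	a55	D	1
a12	a04	A	1
a28	a55	L	1
a36	a39	L	1
a39	a15	D	1
a14	a55	A	1
a12	a05	A	1
a03	a05	A	1
a28	a04	A	1
a55	a39	A	1
a39	a61	L	1
a53	a37	D	1
a05	a47	A	0
a53	a03	D	1
a24	a05	A	1
a45	a15	A	1
a37	a45	A	1
a12	a03	A	1
a05	a37	D	1
a42	a39	A	1
a15	a04	A	1
a39	a33	D	1
a52	a05	A	1
a28	a37	D	1
a55	a45	D	1
a39	a52	D	1
a33	a42	A	1
a55	a47	A	1
a14	a45	A	1
a53	a15	A	1
a36	a15	L	1
a24	a39	L	1
a37	a28	A	0
a47	a13	L	1
a55	a05	A	1
a33	a53	A	1
a24	a07	D	1
a61	a05	L	0
a47	a53	L	1
a42	a04	A	1
a13	a26	D	1
a37	a15	A	1
a28	a15	A	1
a61	a53	D	0
a33	a15	A	1
a33	a45	A	1
a03	a15	A	0
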