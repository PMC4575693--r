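name	structural_type	hierarchy_level	module	hub
a01	4	NA	auditory	FALSE
a02	NA	NA	somatosensory-motor	FALSE
a03	3	6	visual	FALSE
a04	1	10	somatosensory-motor	FALSE
a05	1	10	fronto-limbic	FALSE
a06	NA	NA	NA	NA
a07	5	2	visual	FALSE
a08	3	NA	auditory	FALSE
a09	NA	NA	NA	NA
a10	2	NA	NA	NA
a11	NA	NA	NA	NA
a12	2	8	somatosensory-motor	TRUE
a13	5	2	visual	FALSE
a14	5	1	visual	FALSE
a15	2	8	fronto-limbic	TRUE
a16	3	NA	somatosensory-motor	FALSE
a17	NA	NA	NA	NA
a18	4	NA	auditory	FALSE
a19	5	NA	auditory	FALSE
a20	3	NA	somatosensory-motor	FALSE
a21	NA	NA	NA	NA
a22	5	NA	auditory	FALSE
a23	3	NA	somatosensory-motor	FALSE
a24	4	3	auditory	FALSE
a25	NA	NA	somatosensory-motor	FALSE
a26	5	2	visual	FALSE
a27	4	NA	auditory	FALSE
a28	4	6	auditory	FALSE
a29	2	NA	somatosensory-motor	TRUE
a30	5	NA	auditory	FALSE
a31	1	NA	somatosensory-motor	FALSE
a32	1	NA	somatosensory-motor	FALSE
a33	4	3	auditory	FALSE
a34	2	NA	somatosensory-motor	TRUE
a35	5	NA	auditory	FALSE
a36	1	10	fronto-limbic	FALSE
a37	4	3	auditory	TRUE
a38	2	NA	somatosensory-motor	FALSE
a39	1	10	fronto-limbic	FALSE
a40	NA	NA	auditory	FALSE
a41	NA	NA	auditory	FALSE
a42	2	8	fronto-limbic	TRUE
a43	2	NA	somatosensory-motor	FALSE
a44	2	NA	somatosensory-motor	FALSE
a45	4	4	auditory	TRUE
a46	NA	NA	NA	NA
a47	3	5	visual	FALSE
a48	3	NA	somatosensory-motor	FALSE
a49	NA	NA	NA	NA
a50	NA	NA	auditory	FALSE
a51	NA	NA	NA	NA
a52	2	9	fronto-limbic	FALSE
a53	3	7	auditory	TRUE
a54	NA	NA	NA	NA
a55	3	6	fronto-limbic	TRUE
a56	4	NA	auditory	FALSE
a57	2	NA	somatosensory-motor	FALSE
a58	NA	NA	NA	NA
a59	2	NA	somatosensory-motor	TRUE
a60	3	NA	somatosensory-motor	TRUE
a61	1	10	fronto-limbic	FALSE
a62	NA	NA	NA	NA
a63	1	NA	somatosensory-motor	FALSE
a64	5	NA	auditory	FALSE
a65	5	NA	auditory	FALSE
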