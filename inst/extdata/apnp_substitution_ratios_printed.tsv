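ap	S	Q	N	T	C	G	A	H	M	Y	F	V	L	P	I	W	D	E	K	R
S	-	1.50	1.21	0.82	0.70	0.92	0.90	1.42	1.15	1.91	1.15	0.97	1.18	0.97	1.45	1.64	1.28	1.14	1.42	1.34
Q	0.66	-	0.85	0.66	0.38	0.71	0.61	1.00	0.73	1.91	0.94	0.86	0.89	0.66	1.20	1.06	0.65	0.91	0.82	0.81
N	0.83	1.18	-	0.55	0.59	0.74	0.65	1.39	0.58	1.67	0.62	0.98	0.98	0.83	0.88	1.43	0.71	0.81	0.72	0.94
T	1.23	1.51	1.81	-	1.00	1.17	1.16	1.70	0.95	2.34	1.14	1.26	1.24	1.14	1.78	2.80	1.45	1.52	1.31	1.69
C	1.42	2.67	1.70	1.00	-	1.04	1.32	1.71	1.00	1.10	1.82	1.55	0.98	0.80	1.69	0.70	0.37	0.60	0.67	1.13
G	1.09	1.41	1.34	0.86	0.96	-	1.05	1.14	1.22	3.67	0.93	1.05	0.96	1.02	1.56	1.94	0.95	0.97	0.99	1.18
A	1.11	1.63	1.53	0.86	0.76	0.95	-	1.41	1.26	2.40	1.13	1.19	1.22	0.89	1.29	1.60	0.96	1.01	1.20	1.13
H	0.71	1.00	0.72	0.59	0.58	0.87	0.71	-	0.83	2.14	1.09	0.79	1.22	1.02	0.84	1.19	0.71	0.81	1.36	0.78
M	0.87	1.36	1.71	1.06	1.00	0.82	0.79	1.21	-	1.96	1.15	1.05	1.11	0.57	1.14	1.82	1.26	1.13	1.12	1.20
Y	0.52	0.52	0.60	0.43	0.91	0.27	0.42	0.47	0.51	-	0.77	0.46	0.53	0.46	0.76	0.39	0.47	0.43	0.40	0.53
F	0.87	1.06	1.61	0.88	0.55	1.07	0.88	0.92	0.87	1.30	-	0.94	0.99	0.81	1.24	0.87	0.72	0.88	0.88	0.64
V	1.03	1.16	1.02	0.80	0.65	0.95	0.84	1.27	0.95	2.18	1.06	-	1.22	0.93	1.19	1.66	0.78	1.04	1.17	0.97
L	0.85	1.12	1.02	0.81	1.02	1.05	0.82	0.82	0.90	1.88	1.01	0.82	-	0.93	1.08	1.28	0.85	0.81	1.15	0.84
P	1.03	1.51	1.21	0.88	1.25	0.98	1.12	0.98	1.76	2.19	1.23	1.08	1.07	-	2.03	1.40	1.20	1.20	1.11	1.20
I	0.69	0.83	1.13	0.56	0.59	0.64	0.77	1.19	0.88	1.31	0.81	0.84	0.93	0.49	-	1.12	0.65	0.77	0.81	0.78
W	0.61	0.95	0.70	0.36	1.43	0.51	0.63	0.84	0.55	2.60	1.15	0.60	0.78	0.71	0.89	-	0.36	0.65	0.90	0.63
D	0.78	1.53	1.41	0.69	2.71	1.05	1.04	1.41	0.79	2.11	1.38	1.29	1.17	0.84	1.54	2.75	-	1.11	0.90	1.09
E	0.88	1.10	1.24	0.66	1.67	1.04	0.99	1.24	0.89	2.31	1.13	0.96	1.23	0.83	1.30	1.53	0.90	-	1.12	1.09
K	0.71	1.22	1.40	0.76	1.50	1.01	0.84	0.73	0.89	2.50	1.14	0.85	0.87	0.90	1.23	1.11	1.11	0.89	-	0.87
R	0.75	1.24	1.06	0.59	0.89	0.84	0.88	1.28	0.83	1.89	1.57	1.03	1.19	0.83	1.28	1.60	0.92	0.92	1.15	-
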