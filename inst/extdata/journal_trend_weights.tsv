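journal	specialty	weight_1997	weight_2002	weight_2007	printed_trend	self_consistent
BMJ	Cardiology	3.98	4.28	4.32	8	0
BMJ	Neurology	7.06	5.07	5.17	-27	1
BMJ	Environment and public health	6.61	6.54	7.00	6	1
BMJ	Cancerology	2.35	2.72	3.26	39	1
BMJ	Infectious diseases	3.25	2.97	3.49	7	1
BMJ	Epidemiology	5.38	5.83	5.69	6	1
BMJ	Allergy and immunology	2.89	1.96	2.34	-19	1
BMJ	Vascular medicine and surgery	2.66	1.62	1.63	-39	1
BMJ	Haematology	1.47	2.08	1.60	9	1
BMJ	Surgery	2.19	2.76	2.77	27	0
BMJ	Gastroenterology	2.14	1.78	1.37	-36	1
BMJ	Psychiatry	3.49	4.12	4.80	38	1
BMJ	Pulmonary disease	1.91	1.85	1.83	-4	1
BMJ	Genetics	1.75	1.92	2.72	56	0
BMJ	Pediatrics	2.09	2.49	2.72	30	1
JAMA	Cardiology	4.28	6.15	11.2	161	0
JAMA	Neurology	5.07	7.54	4.24	-16	1
JAMA	Environment and public health	6.54	7.10	5.70	-13	1
JAMA	Cancerology	2.72	3.33	4.73	74	1
JAMA	Infectious diseases	2.97	6.28	3.13	5	1
JAMA	Epidemiology	5.83	3.80	5.49	-6	1
JAMA	Allergy and immunology	1.96	2.87	2.26	16	0
JAMA	Vascular medicine and surgery	1.62	3.15	5.35	231	0
JAMA	Haematology	2.08	1.96	3.72	79	1
JAMA	Surgery	2.76	2.89	2.82	2	1
JAMA	Gastroenterology	1.78	1.86	1.77	0	0
JAMA	Psychiatry	4.12	4.36	2.71	-34	1
JAMA	Pulmonary disease	1.85	2.58	2.43	32	0
JAMA	Genetics	1.92	1.39	3.13	63	1
JAMA	Pediatrics	2.49	1.96	1.08	-57	1
Lancet	Cardiology	7.08	6.85	4.87	-31	1
Lancet	Neurology	7.94	6.26	6.25	-21	1
Lancet	Environment and public health	4.58	6.64	9.47	107	1
Lancet	Cancerology	5.07	5.61	4.58	-10	1
Lancet	Infectious diseases	6.74	4.98	4.01	-41	1
Lancet	Epidemiology	4.21	4.59	8.50	102	1
Lancet	Allergy and immunology	5.46	5.41	3.37	-38	1
Lancet	Vascular medicine and surgery	4.18	3.45	2.40	-43	1
Lancet	Haematology	3.19	3.41	3.19	0	1
Lancet	Surgery	2.17	2.86	1.96	-10	1
Lancet	Gastroenterology	3.50	3.61	1.94	-45	1
Lancet	Psychiatry	2.10	1.86	2.77	32	1
Lancet	Pulmonary disease	2.43	2.81	2.03	-17	0
Lancet	Genetics	3.61	2.90	0.88	-76	1
Lancet	Pediatrics	2.62	2.45	3.81	45	1
NEJM	Cardiology	9.86	8.41	9.23	-6	1
NEJM	Neurology	6.38	6.21	5.86	-8	1
NEJM	Environment and public health	2.33	2.67	3.35	44	1
NEJM	Cancerology	7.61	5.60	10.18	34	1
NEJM	Infectious diseases	5.46	6.19	4.34	-20	0
NEJM	Epidemiology	1.47	2.38	1.85	26	1
NEJM	Allergy and immunology	5.81	5.46	5.56	-4	1
NEJM	Vascular medicine and surgery	5.48	4.34	5.41	-1	1
NEJM	Haematology	4.64	4.24	4.51	-3	1
NEJM	Surgery	3.37	3.97	3.29	-2	1
NEJM	Gastroenterology	4.33	3.97	3.44	-21	1
NEJM	Psychiatry	1.01	1.67	1.18	17	1
NEJM	Pulmonary disease	2.86	4.54	4.53	58	1
NEJM	Genetics	2.77	2.85	3.18	15	1
NEJM	Pediatrics	1.83	2.83	1.85	1	1
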