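measurand	age_months	cpko_mean	cpko_sd	wt_mean	wt_sd	fc_printed	p_printed	fc_aging_cpko	p_aging_cpko	fc_aging_wt	p_aging_wt
IHLC	6	0.082	0.028	0.041	0.023	2.00	0.0342	1.88	0.0645	2.49	0.0131
IHLC	10	0.154	0.07	0.102	0.036	1.51	NS	1.88	0.0645	2.49	0.0131
TG	6	0.00086	0.0009	0.0003	0.0002	3.07	0.0635	1.64	NS	3.11	0.0014
TG	10	0.00141	0.0011	0.0009	0.0002	1.62	NS	1.64	NS	3.11	0.0014
SI	6	10.50	5.12	9.88	2.46	1.06	NS	0.79	NS	1.06	NS
SI	10	8.34	4.46	10.50	2.62	0.79	NS	0.79	NS	1.06	NS
ndb	6	0.56	0.35	0.47	0.55	1.19	NS	1.39	NS	1.87	NS
ndb	10	0.78	0.54	0.88	0.93	0.89	NS	1.39	NS	1.87	NS
UFA	6	0.84	0.13	0.69	0.25	1.53	NS	0.69	0.0486	1.51	NS
UFA	10	0.58	0.21	1.04	0.29	0.56	0.0225	0.69	0.0486	1.51	NS
SFA	6	0.14	0.14	0.31	0.25	0.45	NS	2.97	0.0422	0.54	NS
SFA	10	0.42	0.21	0.17	0.17	2.47	0.0766	2.97	0.0422	0.54	NS
PUFA	6	0.70	0.46	0.52	0.08	1.35	NS	0.31	0.0079	0.75	NS
PUFA	10	0.22	0.09	0.39	0.41	0.56	NS	0.31	0.0079	0.75	NS
MUFA	6	0.34	0.31	0.41	0.11	0.84	NS	0.91	NS	1.22	NS
MUFA	10	0.31	0.22	0.5	0.42	0.61	NS	0.91	NS	1.22	NS
MCL	6	18.06	5.15	16.37	3.57	1.1	NS	0.84	NS	1.14	NS
MCL	10	15.16	5.60	18.71	3.34	0.81	NS	0.84	NS	1.14	NS
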