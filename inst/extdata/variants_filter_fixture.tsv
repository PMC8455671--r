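patient_id	timepoint	gene	protein_change	consequence	classification	vaf_pct	mut_copies_per_ml	total_copies_per_ml	coverage	fwd_fraction
P001	baseline	PIK3CA	p.H1047R	missense	pathogenic	5.0	50	1000	90	0.50
P001	baseline	PIK3CA	p.E545K	missense	pathogenic	5.0	50	1000	100	0.50
P002	baseline	ESR1	p.D538G	missense	pathogenic	8.0	80	1000	500	0.05
P002	baseline	ESR1	p.Y537N	missense	pathogenic	8.0	80	1000	500	0.95
P003	baseline	TP53	p.=	silent	vus	2.0	20	1000	500	0.50
P003	baseline	TP53	p.?	intronic	vus	2.0	20	1000	500	0.50
P004	baseline	PIK3CA	p.H1047R	missense	pathogenic	6.0	60	1000	500	0.50
P004	baseline	AKT1	p.E17K	frameshift	pathogenic	3.0	30	1000	101	0.10
P005	baseline	TP53	p.R175H	splice	pathogenic	4.0	40	1000	500	0.90
P005	d14	TP53	p.R175H	nonsense	pathogenic	1.0	10	1000	500	0.60
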