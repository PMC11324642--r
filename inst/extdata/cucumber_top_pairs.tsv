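gene1	gene2	control_cor	control_pVal	stress_cor	stress_pVal	zScoreDiff	pValDiff	Classes
LOC101209599	LOC101221250	-0.00583	0.981689	0.985479	9.50E-14	6.750255	1.48E-11	0/+
LOC101209599	LOC101216320	-0.28072	0.259164	0.971161	2.20E-11	6.574823	4.87E-11	0/+
LOC101205971	LOC105435136	-0.715110	0.00085	0.807402	5.10E-05	5.524036	3.31E-08	-/+
LOC101204590	LOC101207749	0.708786	0.000991	-0.8021	6.22E-05	-5.44772	5.10E-08	+/-
LOC101216320	LOC101221250	0.392644	0.107014	0.983571	2.54E-13	5.427623	5.71E-08	0/+
LOC101205805	LOC101217277	-0.46192	0.053628	0.88249	1.26E-06	5.166829	2.38E-07	0/+
LOC101206172	LOC101209599	0.010636	0.966589	0.950915	1.45E-09	5.013351	5.35E-07	0/+
LOC101203084	LOC101206142	-0.36789	0.133089	0.893961	5.74E-07	5.004244	5.61E-07	0/+
LOC101204590	LOC101221250	-0.21779	0.385305	0.916726	8.93E-08	4.900632	9.55E-07	0/+
LOC101203449	LOC101216320	0.922398	5.17E-08	-0.16899	0.502642	-4.862390	1.16E-06	+/0
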