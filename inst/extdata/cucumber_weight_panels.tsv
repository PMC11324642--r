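method	gene_id	weight
correlation	LOC101213801	1
correlation	LOC101210665	0.981792
correlation	LOC101205805	0.976468
correlation	LOC101217277	0.965222
correlation	LOC101213872	0.961903
correlation	LOC101222503	0.95507
correlation	LOC101206239	0.950225
correlation	LOC101206201	0.947782
correlation	LOC101212424	0.946504
correlation	LOC101212625	0.946377
correlation	LOC101203084	0.936201
correlation	LOC101204590	0.929242
correlation	LOC101210747	0.921718
correlation	LOC101214385	0.919868
correlation	LOC101213580	0.9143
correlation	LOC116403322	0.91381
correlation	LOC101205431	0.913398
correlation	LOC101210491	0.903276
correlation	LOC105435194	0.902187
correlation	LOC101204309	0.901909
correlation	LOC101205898	0.900742
svm	WRKY34	1
svm	LOC105435136	0.955122
svm	LOC101222803	0.929876
svm	LOC101213580	0.927133
svm	LOC101212625	0.926384
svm	LOC101206142	0.922183
svm	LOC101223041	0.908447
svm	LOC101202985	0.908386
svm	LOC101207749	0.905523
svm	LOC116406191	0.902036
uncertainty	LOC101221250	1
uncertainty	LOC101209599	0.956375
uncertainty	LOC101216320	0.931761
uncertainty	LOC101206172	0.910819
relief	LOC101213801	1
relief	LOC101205971	0.964735
relief	LOC101214385	0.925444
relief	LOC101203449	0.924483
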