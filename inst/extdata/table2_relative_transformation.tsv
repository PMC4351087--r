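# Published relative-transformation values (mean +/- SD) for the oligo
# creating a T-C mispair at its 3' terminus in the G148T reporter strains,
# by strain genotype and reporter orientation. Data fixture for the
# rendering rules only: the underlying per-replicate colony counts are not
# published, so these values are not recomputable.
oligo_id	allele	orientation	target_strand	genotype	mean	sd
148C	G148T	F	leading	msh6	0.01	0.00
148C	G148T	F	leading	msh6 pol2-4	0.04	0.00
148C	G148T	F	leading	msh6 pol3-5DV+/-	0.08	0.07
148C	G148T	F	leading	msh6 pol3-5DV	2.3	1.5
148C	G148T	R	lagging	msh6	0.25	0.23
148C	G148T	R	lagging	msh6 pol2-4	0.20	0.01
148C	G148T	R	lagging	msh6 pol3-5DV+/-	1.3	0.7
148C	G148T	R	lagging	msh6 pol3-5DV	7.0	4.1
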