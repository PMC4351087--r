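# Published het/hom reversion-rate ratio table: ratio of homozygous to
# heterozygous proofreading-deficient reversion rates per allele and
# orientation. pol2_significant marks Pol epsilon comparisons whose 83%
# confidence intervals did not overlap (P ~ 0.05); all Pol delta
# comparisons were significant with non-overlapping 95% intervals.
allele	orientation	pol2_ratio	pol2_significant	pol3_ratio
G148T	F	2.2	TRUE	32
G148T	R	2.4	FALSE	46
A149C	F	1.6	TRUE	12
A149C	R	2.0	TRUE	32
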