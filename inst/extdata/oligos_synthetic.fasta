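>148C_synthetic 3prime=C strand=variable synthetic 40-mer; terminal C creates a T/C mispair (template/primer)
ACGTTGCATCAGGTACCTTAGCATGGAATCCGATTGGAAC
>148G_synthetic 3prime=G strand=variable synthetic 40-mer; terminal G creates an A/G mispair
TGCAACGTAGTCCATGGAATCGTACCTTAGGCTAACCTAG
>149A_synthetic 3prime=A strand=variable synthetic 40-mer; terminal A creates a G/A mispair
CATGGTACCTTAGCATCAGGACGTTGCATCCGATTGGATA
>149T_synthetic 3prime=T strand=variable synthetic 40-mer; terminal T creates a C/T mispair
GGAATCGTACCTTAGGCTAATGCAACGTAGTCCATGCCTT
>148oxoG_synthetic 3prime=oxoG strand=variable synthetic 40-mer; same sequence as 148G but 3' base is 8-oxoG (A/oxoG mispair, proofreading-exempt)
TGCAACGTAGTCCATGGAATCGTACCTTAGGCTAACCTAG
>Trpwt40_synthetic 3prime=internal strand=variable synthetic internal-mismatch control oligo
ACGTTGCATCAGGTACCTTAGCATGGAATCCGATTGGTTG
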