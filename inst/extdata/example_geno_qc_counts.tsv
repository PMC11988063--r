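stage	unit	threshold	screened	retained	dropped
duplicate animals	animal	genotype r > 0.98	1478	1478	0
animal call rate	animal	> 0.90	1478	1477	1
SNP call rate and MAF	snp	call rate > 0.95, MAF > 0.01	49911	45682	4229
autosomal markers	snp	remove X, Y, MT markers	49911	40822	9089
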