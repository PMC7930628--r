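##fileformat=VCFv4.2
##source=external-caller
##contig=<ID=MT,length=16569>
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ancient1
MT	152	.	T	C	.	PASS	.	AD:DP:AF	5,95:100:0.95
MT	3107	.	N	C	.	.	.	AD:DP:AF	48,2:50:0.04
MT	8860	.	A	G	.	PASS	.	AD:DP:AF	52,48:100:0.48
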