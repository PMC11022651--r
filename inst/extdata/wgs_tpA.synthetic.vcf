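##fileformat=VCFv4.2
##INFO=<ID=ANN,Number=1,Type=String,Description="Consequence|Gene">
##contig=<ID=chr2>
##contig=<ID=chr4>
##contig=<ID=chr20>
##contig=<ID=chr22>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr2	25235778	.	C	G	60	PASS	ANN=missense_variant|DNMT3A
chr2	25234347	.	G	C	60	PASS	ANN=missense_variant|DNMT3A
chr2	25241591	.	C	A	60	PASS	ANN=missense_variant|DNMT3A
chr2	25241591	.	C	A	60	PASS	ANN=splice_region_variant|DNMT3A
chr4	105275662	.	G	T	60	PASS	ANN=missense_variant|TET2
chr22	28734438	.	C	T	60	PASS	ANN=missense_variant|CHEK2
chr20	32434638	.	AG	A	60	PASS	ANN=frameshift_variant|ASXL1
chr2	25300000	.	T	C	60	PASS	ANN=intron_variant|DNMT3A
chr2	25300100	.	T	C	60	PASS	ANN=intron_variant|DNMT3A
chr2	25300100	.	T	G	60	PASS	ANN=intron_variant|DNMT3A
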