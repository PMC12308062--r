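family	gene	genomic	cdna	protein	zygosity	cadd	gnomad_af	classification	note
EX1	FAM83H	chr8:g.144811323G>A	c.601C>T	p.(Gln201*)	het	40	0.0024	B	Recurrent truncating variant in an upstream FAM83H coding exon; population frequency too high for dominant disease and outside the last-exon interval. Genomic coordinate is synthetic (approximate placement upstream of the last-exon boundary).
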