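gene	rule	contig	start	end	note
FAM83H	truncating_last_exon_only	chr8	144806102	144811000	Truncating (nonsense/frameshift) FAM83H variants qualify only inside the large last coding exon; interval is an approximation of that exon (0-based half-open, hg19) chosen to separate last-exon variants from upstream-exon truncations.
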