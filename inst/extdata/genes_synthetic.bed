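# Synthetic gene intervals for examples and tests (BED: 0-based half-open).
# MUC4 follows the hg19 reference span; the PELI2 interval is a synthetic
# stand-in chosen to contain the rs8003149 fixture position.
3	195746764	195812053	MUC4
14	56085000	56295000	PELI2
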