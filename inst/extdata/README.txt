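macrodomains_example.bed: approximate, literature-derived example intervals
for the E. coli MG1655 macrodomains (Ori, Ter, Left, Right) and the two
non-structured regions, on a linearised U00096 coordinate system (0-based
half-open BED).  These are illustrative values for running the package
examples; users comparing conditions on real data should supply their own
verified intervals.
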