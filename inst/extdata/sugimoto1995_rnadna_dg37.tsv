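# Nearest-neighbor stacking free energies for RNA/DNA hybrid duplexes,
# dG37 in kcal/mol (Sugimoto et al. 1995, solution hybridization).
# Keys are the DNA probe-strand dinucleotide read 5'->3'; the value is the
# stack formed with the antiparallel complementary RNA dinucleotide
# (probe 5'-XY-3' paired with target RNA 5'-revcomp(XY)-3', T->U).
# INIT is the duplex initiation term.
AA	-0.2
AC	-1.1
AG	-0.9
AT	-0.9
CA	-1.6
CC	-2.9
CG	-1.7
CT	-1.8
GA	-1.5
GC	-2.7
GG	-2.1
GT	-2.1
TA	-0.6
TC	-1.3
TG	-0.9
TT	-1.0
INIT	3.1
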