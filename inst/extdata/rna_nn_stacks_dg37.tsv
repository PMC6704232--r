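# Watson-Crick RNA nearest-neighbor stacking free energies, dG37 (kcal/mol)
# Xia et al. 1998 / Turner 2004 parameter set. Key = dinucleotide read
# 5'->3' on one strand of the stack; the paired strand is its reverse
# complement, so each key and its reverse complement share one value.
# format: stack<TAB>dg37
stack	dg37
AA	-0.93
UU	-0.93
AU	-1.10
UA	-1.33
CU	-2.08
AG	-2.08
CA	-2.11
UG	-2.11
GU	-2.24
AC	-2.24
GA	-2.35
UC	-2.35
CG	-2.36
GG	-3.26
CC	-3.26
GC	-3.42
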