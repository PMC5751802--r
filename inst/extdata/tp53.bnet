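# Simplified p53/Mdm2 Boolean network (5 nodes).
# dna_dsb is the DNA double-strand-break input signal.
dna_dsb = INPUT
ATM = !Wip1 & (ATM | dna_dsb)
P53 = !Mdm2 & (ATM | Wip1)
Wip1 = P53
Mdm2 = !ATM & (P53 | Wip1)
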