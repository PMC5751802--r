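# NSCLC signaling network (8 nodes); EGFR, KRAS and P53 are unregulated
# inputs in this model.
EGFR = INPUT
PIK3CA = EGFR | KRAS
AKT = PIK3CA
KRAS = INPUT
RAF1 = KRAS & !AKT
BAD = !AKT
P53 = INPUT
BCL2 = !BAD | !P53
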