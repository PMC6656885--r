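# Domain-name normalization map: raw annotation name -> canonical name.
# Edit or extend to match the Pfam release in use.
NB-ARC: NBS
NBS: NBS
NB-LRR: NBS
AAA: NBS
LRR_1: LRR
LRR_2: LRR
LRR_3: LRR
LRR_4: LRR
LRR_5: LRR
LRR_6: LRR
LRR_8: LRR
LRR_9: LRR
LRRNT_2: LRR
LRR: LRR
TIR: TIR
TIR_2: TIR
PF01582: TIR
CC: CC
Coil: CC
coiled_coil: CC
RPW8: CC
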