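pair_id,ligand,receptor,pathway
SPP1_CD44,SPP1,CD44,SPP1
SPP1_ITGA4_ITGB1,SPP1,ITGA4+ITGB1,SPP1
FN1_CD44,FN1,CD44,FN1
FN1_ITGA4_ITGB1,FN1,ITGA4+ITGB1,FN1
FN1_ITGA4_ITGB7,FN1,ITGA4+ITGB7,FN1
TGFB1_TGFBR1_TGFBR2,TGFB1,TGFBR1+TGFBR2,TGFb
IL6_IL6R,IL6,IL6R,IL6
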