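pair_id,ligand,receptor,source_annotation
TNF_TNFRSF1A,TNF,TNFRSF1A,curated
IL1B_IL1R1,IL1B,IL1R1,curated
TGFB1_TGFBR1,TGFB1,TGFBR1,curated
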