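# Demonstration run: simulate both modalities at reduced scale and execute
# the full pipeline. Equivalent to demoPipelineConfig(seed = 1).
seed: 1
sim:
  nCellsPerTimepoint: 120
  nGenes: 600
  nMarkersPerType: 10
  nSpots: 100
sc_p_threshold: 1.0e-10
perm:
  nPermutations: 200
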