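# Example pipeline configuration: a small synthetic study that runs the
# whole simulate -> deg -> response -> aberrancy -> trends chain in a few
# seconds.  Omitted keys keep their defaults.
seed: 1
synth:
  nGenes: 400
  nSets: 6
  setSizeRange: [10, 20]
  nTFs: 4
  tusPerTF: 3
  genesPerTU: 2
  nToleranceGenes: 60
  nRegionGenes: 15
pipeline:
  alpha: 0.05
  fcThreshold: 1.2
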