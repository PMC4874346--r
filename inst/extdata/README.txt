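synthetic_phylo_distances.csv
  SYNTHETIC placeholder phylogenetic distance matrix over the six simulated
  carnivore species, on an approximate pairwise-divergence scale (2 x
  divergence time, Myr) consistent with the consensus carnivore topology
  (Panthera pair closest; Felidae; Hyaenidae; Caniformia outgroup). These
  are NOT measured supertree distances; real analyses must supply their own
  matrix (labelled square CSV or Newick tree).
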