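# Three sampled values (low / medium / high) per parameter dimension of the
# synthetic species grid (3^7 = 2187 species). Values are drawn from
# literature-typical ranges for hippocampal pyramidal neurons; units are
# seconds, micrometres and absolute molecule counts throughout.
#
# These levels are configuration, not code: edit this file (or pass your own
# via grid_sample(levels = ...)) to explore other sampling schemes.
dimensions:
  mrna_halflife:        # mRNA half-life (s): ~2 h to ~30 h
    levels: [7200, 36000, 108000]
  noncoding_ratio:      # non-coding / coding nucleotide ratio (dimensionless)
    levels: [0.25, 1.0, 4.0]
  protein_halflife:     # protein half-life (s): 2 d / 8 d / 32 d (in vivo range)
    levels: [172800, 691200, 2764800]
  protein_aa:           # amino acids per protein
    levels: [100, 450, 1500]
  spine_capacity:       # maximal protein copies per spine (eta_p)
    levels: [100, 1000, 10000]
  protein_diffusion:    # protein diffusion constant (um^2/s)
    levels: [0.01, 0.1, 1.0]
  transport_theta:      # instantaneous fraction of dendritic mRNA granules in
    levels: [0.02, 0.05, 0.15]   # motor-driven transit (live-imaging range)
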