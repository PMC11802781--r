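# Project-wide defaults. Units: seconds, micrometres, ATP; counts are absolute
# molecule numbers; linear densities are per um of dendrite.
geometry:
  L: 250          # dendrite length (um)
  rho: 1          # spine density (spines/um)
  phi: 0.95       # minimal spine filling ratio at equilibrium
  grid_dx: 1      # spatial step (um)

rates:
  tau: 0.01       # translation rate (proteins per mRNA per s)
  u_p: 1.0e-3     # spine entry rate (1/s)
  nu_p: 2.0e-4    # spine exit rate (1/s); ~80 min spine residence

diffusion:
  D_m0: 0.005     # diffusion constant of non-transported mRNA (um^2/s)
  D_p: 0.05       # default protein diffusion constant (um^2/s)

transport:
  v: 1.0          # instantaneous run velocity (um/s)
  beta: 0.5       # run termination rate (1/s); mean run duration 2 s
  theta: 0.05     # default transported mRNA fraction (sets alpha)
  v_bias: 0.0     # net anterograde drift (um/s)

costs:
  C_nt: 2.17      # ATP per transcribed nucleotide
  C_aa: 5         # ATP per amino acid (synthesis + degradation)
  C_cargo: 125    # ATP/s to move one cargo at 1 um/s
  v_ref: 1.0      # reference cargo speed (um/s) for the cost constant

scenario:
  r_soma_grid: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
  mrnas_per_granule: 1

# Named species presets. Half-lives/lengths/copy numbers are printed
# experimental values; diffusion, spine-exchange and transport entries are
# PROVISIONAL literature-range choices (see the methods vignette).
presets:
  camkii:
    name: CaMKIIa
    N_aa: 478
    N_nt: 4900
    eta_p: 32336
    halflife_m: 72000      # ~20 h
    halflife_p: 691200     # ~8 d
    tau: 0.01
    D_p: 0.05
    D_m0: 0.005
    u_p: 1.0e-3
    nu_p: 2.0e-4
    transport: {v: 1.0, beta: 0.5, theta: 0.05}
  shank3:
    name: Shank3
    N_aa: 1730
    N_nt: 7500
    eta_p: 300
    halflife_m: 43200      # ~12 h
    halflife_p: 846720     # ~9.8 d
    tau: 0.01
    D_p: 0.1
    D_m0: 0.005
    u_p: 5.0e-3
    nu_p: 2.5e-4
    transport: {v: 1.0, beta: 0.5, theta: 0.0}
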