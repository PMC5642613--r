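# Default pan-cancer discovery fixture: one 42-gene immunoglobulin-like
# module (within-module CC 0.9) plus a 21-gene companion module (CC 0.85)
# against 500 uncorrelated background genes, 300 samples across 6 entities
# with an HCC-like entity of 45 samples.  The companion module makes the
# cluster-number search well-posed (true k = 2); the 42-gene module is the
# analysed analogue.
n_background_genes: 500
n_samples: 300
noise_sd: 1.0
planted_modules:
  - size: 42
    within_cc: 0.9
  - size: 21
    within_cc: 0.85
entities:
  HCC: 45
  E01: 51
  E02: 51
  E03: 51
  E04: 51
  E05: 51
hcc_entity: HCC
gene_mean: 8.0
gene_mean_sd: 1.5
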