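# Example end-to-end configuration: simulate a small two-condition
# methylome with injected CHH DMRs and run every stage on it.
simulate:
  enabled: true
  n_chroms: 1
  chrom_length: 300000
  coverage_mean: 14
  n_replicates: 3
  n_genes: 120
  n_tes: 150
  n_injections: 30
  injection_width: 500
  injection_context: CHH
  injection_delta: -30
  effect: 4
  noise_sd: 0.5
  seed: 11
conditions: [OG, SD]
dmr:
  window_size: 200
  step: 100
  min_site_coverage: 3
  p_threshold: 0.01
  sda_threshold: {CG: 10, CHG: 10, CHH: 5}
  min_abs_delta: 5
  test: student
association:
  flank: 2000
integration:
  contexts: [CHH]
  min_abs_ratio: 1.5
density:
  bin_size: 50000
det_alpha: 0.01
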