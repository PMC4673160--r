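# Seeded end-to-end demonstration configuration: simulate a cohort with
# the default tumor shift, deconvolve identifiable isoform groups from
# exon signals (exon 6 unmeasured), and run the qPCR analyses.
seed: 1
out_dir: opnsplice-out
simulate:
  n_per_class: 20
  probe_noise_sd: 0.1
deconvolution:
  k_proxies: 3
  observed_exons: [1, 2, 3, 4, 5, 7, 8]
  method: subtraction
qpcr:
  target: SPP1
  references: [GAPDH, ACTB, RPLP0]
  calibrator_classes: [Normal]
  reference_classes: [Normal, BE]
plots: false
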