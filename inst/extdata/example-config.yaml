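# Example pipeline configuration (synthetic cohort).
# Run:  Rscript inst/cli/cqrmr fit --config example-config.yaml --out results/
simulate:
  n_individuals: 5000
  variants:
    - variant_id: rsA
      maf: 0.30
      effect_model: location_scale
      beta: -0.2
      theta: 0.15
    - variant_id: rsB
      maf: 0.25
      effect_model: location
      beta: -0.2
    - variant_id: rsC
      maf: 0.15
grid: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
n_boot: 200
calibration:
  n_snps: 200        # null SNPs for the genomic-control factors
  maf_range: [0.05, 0.45]
prs: false
min_hom: 50
alpha: 0.05
seed: 1
out_dir: results
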