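# Example pipeline configuration for run_pipeline() via read_run_config().
# Any run_config() field can appear here; a nested `sim` block overrides
# sim_config() defaults. Flags passed to read_run_config(...) win over the
# file.
seed: 1
outdir: regulomer_demo
min_support: 2
tau: 1.0
pseudocount: 0.5
ranked_bins: 11
padj_pair: 0.1
padj_lrt: 0.05
p53_cutoff: 17
som_grid: [8, 8]
metacluster_k: 10
sim:
  n_genes: 800
  n_true_sites: 600
  n_events: 5000
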