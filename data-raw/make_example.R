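# Regenerates the small synthetic example screen shipped under inst/extdata/.
# 100 genes x 3 sgRNAs, 3 true hits per effect level, two replicates.
library(screenperm)

sim <- simulate_screen(sim_config(
  n_genes = 100, sgrnas_per_gene = 3, genes_per_level = 3,
  n_replicates = 2, seed = 42
))
write_simulated_screen(
  sim,
  counts_path = "inst/extdata/example_screen_synthetic.tsv",
  truth_path = "inst/extdata/example_truth_synthetic.tsv"
)
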