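#!/usr/bin/env Rscript
# Build and compare contact maps from the simulated libraries: classify
# read pairs by strand-orientation profiles, bin at 5 kb, SCN-normalize,
# call CID boundaries from the directional index (250 kb windows on the
# correlation matrix), quantify the secondary diagonal, and write the
# wild-type / cohesion-null log2 ratio map, SCC matrix and dendrogram.
# Run analysis/01_simulate_hic.R first.

suppressPackageStartupMessages(library(chromarch))
seed <- 20260929
genome <- generate_genome(3210000, circular = TRUE, mean_fragment_bp = 256,
                          bin_size_bp = 5000, seed = seed) # same seed as 01

cfg <- run_config(out_dir = "results/hic/maps", seed = seed)
run_hic(cfg,
        c(wt = "results/hic/wt.pairs",
          cohesion_null = "results/hic/cohesion_null.pairs"),
        genome)

manifest <- jsonlite::read_json("results/hic/maps/manifest.json")
for (nm in c("wt", "cohesion_null")) {
  st <- manifest$stages[[nm]]
  cat(sprintf(
    "%s: thresholds (uncut %s, circle %s); SCN %s iterations; %s boundaries; arm score %.3f\n",
    nm, st$k_uncut, st$k_circle, st$scn_iterations, st$n_boundaries,
    st$arm_score
  ))
}
scc_mat <- read_dense_matrix("results/hic/maps/scc_matrix.tsv")
cat(sprintf("SCC(wt, cohesion_null) = %.4f\n", scc_mat[1, 2]))
cat("The cohesion-null arm score collapsing toward 0 while the wild type\n")
cat("stays high is the replichore-cohesion signature; the ratio map\n")
cat("(results/hic/maps/ratio_wt_vs_cohesion_null.tsv) localizes the loss\n")
cat("to the anti-diagonal band and the anchor cross.\n")
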