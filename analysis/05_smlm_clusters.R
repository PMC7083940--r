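#!/usr/bin/env Rscript
# Cluster the simulated PALM data: filter events on photons/PSF width,
# group blinks (3 on-frames, 0 off, 30 nm), assign events to cells, order
# each cell's events with OPTICS (MinPts 32, eps 3000 nm), cut the
# reachability plot at 50 nm (macroclusters) and 35 nm (subclusters), and
# compare the two conditions with Kruskal-Wallis rank-sum tests on the two
# biggest macroclusters per cell.
# Run analysis/04_simulate_smlm.R first.

suppressPackageStartupMessages(library(chromarch))
cfg <- run_config(out_dir = "results/smlm/clusters")
run_smlm(cfg,
         c(wt = "results/smlm/wt_localizations.csv",
           single_site = "results/smlm/single_site_localizations.csv"),
         c("results/smlm/wt_cells.wkt", "results/smlm/single_site_cells.wkt"))

for (nm in c("wt", "single_site")) {
  st <- read.csv(sprintf("results/smlm/clusters/%s_cluster_stats.csv", nm))
  top <- st[st$top2, ]
  cat(sprintf(
    "%s: %d macroclusters (%d cells); top-2 events/macro median %.0f; subs/macro median %.1f\n",
    nm, nrow(st), length(unique(st$cell_id)), median(top$n_events),
    median(top$n_sub)
  ))
}
cmp <- read.csv("results/smlm/clusters/condition_comparison.csv")
print(cmp, row.names = FALSE)
cat("A higher subcluster count per macrocluster in the wild type than in\n")
cat("the single-site condition mirrors the extra nucleation zones; the\n")
cat("rank-sum test quantifies that difference on the two biggest\n")
cat("macroclusters per cell.\n")
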