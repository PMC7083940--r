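#!/usr/bin/env Rscript
# Simulate two 3C/Hi-C libraries from a C. glutamicum-like 3.21 Mb circular
# chromosome: a wild-type-like condition with the parS-anchored
# replichore-cohesion band plus ori cross signal, and a cohesion-null
# condition (band and cross absent, as seen when the loading site or its
# binding protein is lost). Both carry planted self-circle/uncut noise so
# the event classifier has something to remove.

suppressPackageStartupMessages(library(chromarch))
out <- "results/hic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929

genome <- generate_genome(3210000, circular = TRUE, mean_fragment_bp = 256,
                          bin_size_bp = 5000, seed = seed)
print(genome)

truth_wt <- folding_truth() # band + cross + CIDs, anchor at 3.16 Mb
truth_null <- folding_truth(arm_amplitude = 0, cross_amplitude = 0)

noise <- pair_noise_model(frac_self_circle = 0.05, frac_uncut = 0.10,
                          uncut_max_fragments = 3)
n_pairs <- 2e6 # deep enough for ~10 counts per 5 kb map cell
for (cond in c("wt", "cohesion_null")) {
  truth <- if (cond == "wt") truth_wt else truth_null
  emap <- expected_contact_matrix(genome, truth)
  pairs <- sample_pairs(genome, emap, n_pairs, noise,
                        seed = seed + match(cond, c("wt", "cohesion_null")))
  write_pairs(pairs, file.path(out, paste0(cond, ".pairs")))
  cat(sprintf("%s: %d pairs (%s)\n", cond, nrow(pairs),
              paste(names(table(pairs$true_label)),
                    table(pairs$true_label), sep = "=", collapse = ", ")))
}

# ground truth sidecar for downstream checks
jsonlite::write_json(
  list(genome = list(length_bp = genome$length_bp,
                     n_fragments = genome$n_fragments,
                     bin_size_bp = genome$bin_size_bp),
       wt = unclass(truth_wt), cohesion_null = unclass(truth_null),
       noise = unclass(noise), n_pairs = n_pairs, seed = seed),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA
)
cat("truth written to", file.path(out, "truth.json"), "\n")
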