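# End-to-end workflow drivers chaining the stages into the two reproducible
# pipelines: Hi-C (pairs -> filter -> bin -> normalize -> DI / ratio / SCC /
# arm score) and SMLM (filter -> group -> assign -> OPTICS -> clusters ->
# stats). Every run writes a manifest with parameters and input checksums.

#' Run configuration with the study's default parameters
#'
#' All stage parameters in one flat list. Defaults equal the analysis
#' protocol's stated values where one exists: 5 kb bins, 250 kb directional
#' index windows, alpha 0.05, MinPts 32, epsilon 3000 nm, reachability cuts
#' 50/35 nm, photons 70-350, PSF width 70-170 nm, grouping 3 on-frames / 0
#' off-frames / 30 nm radius, SCC smoothing index 3.
#'
#' @param ... overrides of any default (unknown names are an error).
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    bin_size_bp = 5000, filter_quantile = 0.01, scn_tol = 1e-6,
    scn_max_iter = 200L, saturation_q = 0.995,
    k_max = 50L, orientation_tol = 0.05,
    di_window_bp = 250000, alpha = 0.05,
    smooth_h = 3L, scc_max_dist_bp = 500000,
    arm_anchor_bp = 3160000, band_halfwidth_bins = 2L,
    photon_min = 70, photon_max = 350, psf_min = 70, psf_max = 170,
    group_max_on = 3L, group_max_off = 0L, group_radius_nm = 30,
    minpts = 32L, epsilon_nm = 3000, macro_nm = 50, sub_nm = 35,
    seed = 1L, out_dir = "results"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

write_manifest <- function(path, stage_log, cfg, inputs) {
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  jsonlite::write_json(
    list(parameters = unclass(cfg), input_md5 = checksums, stages = stage_log),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Run the Hi-C workflow on pairs files
#'
#' For each named pairs file: read, profile read-pair orientations, estimate
#' the uncut/self-circle thresholds, classify, bin, mask poor bins, SCN
#' normalize, and write the labeled pairs, raw and normalized maps, the
#' directional-index track with boundary calls, and the secondary-diagonal
#' profile. With two or more samples it also writes log2 ratio maps against
#' the first sample, the pairwise SCC matrix and a Newick dendrogram. The
#' config is validated before any stage runs.
#'
#' @param config a `run_config`.
#' @param pairs_paths named character vector of pairs files.
#' @param genome the `genome_model` the pairs were mapped to.
#' @return (invisibly) the output directory; artifacts and `manifest.json`
#'   are written there.
#' @export
run_hic <- function(config, pairs_paths, genome) {
  stopifnot(inherits(config, "run_config"), inherits(genome, "genome_model"))
  if (2 * config$di_window_bp >= genome$length_bp) {
    stop("directional-index window exceeds half the genome", call. = FALSE)
  }
  missing <- pairs_paths[!file.exists(pairs_paths)]
  if (length(missing)) {
    stop("missing input(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(pairs_paths))) {
    names(pairs_paths) <- sprintf("sample%d", seq_along(pairs_paths))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  maps <- list()
  for (nm in names(pairs_paths)) {
    pairs <- read_pairs(pairs_paths[[nm]])
    prof <- orientation_profile(pairs, genome, config$k_max)
    thr <- estimate_event_thresholds(prof, config$orientation_tol)
    labeled <- classify_pairs(pairs, genome, thr$k_uncut, thr$k_circle)
    write_pairs(labeled, file.path(config$out_dir,
                                   sprintf("%s_labeled.pairs", nm)))
    raw <- bin_contacts(labeled, genome, config$bin_size_bp)
    valid <- filter_bins(raw, config$filter_quantile)
    norm <- scn_normalize(raw, valid, config$scn_tol, config$scn_max_iter)
    write_dense_matrix(raw, file.path(config$out_dir, sprintf("%s_raw.tsv", nm)))
    write_dense_matrix(norm, file.path(config$out_dir, sprintf("%s_norm.tsv", nm)))
    write_valid_bins(valid, file.path(config$out_dir, sprintf("%s_valid.txt", nm)))
    di <- directional_index(correlation_matrix(norm), config$di_window_bp,
                            config$alpha)
    write_di_track(di, file.path(config$out_dir, sprintf("%s_di.tsv", nm)))
    bounds <- call_boundaries(di, config$alpha)
    write_boundaries_bed(bounds, config$bin_size_bp,
                         file.path(config$out_dir, sprintf("%s_boundaries.bed", nm)))
    arm <- secondary_diagonal_strength(norm, config$arm_anchor_bp,
                                       config$band_halfwidth_bins)
    utils::write.table(arm$profile,
                       file.path(config$out_dir, sprintf("%s_arm_profile.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    maps[[nm]] <- norm
    log[[nm]] <- list(
      n_pairs = nrow(pairs), k_uncut = thr$k_uncut, k_circle = thr$k_circle,
      labels = as.list(table(labeled$label)),
      scn_iterations = attr(norm, "iterations"),
      n_boundaries = nrow(bounds), arm_score = arm$score
    )
  }
  if (length(maps) >= 2L) {
    ref <- names(maps)[1]
    for (nm in names(maps)[-1]) {
      rm_ <- log2_ratio(maps[[ref]], maps[[nm]], labels = c(ref, nm))
      write_dense_matrix(rm_$matrix,
                         file.path(config$out_dir,
                                   sprintf("ratio_%s_vs_%s.tsv", ref, nm)))
    }
    cl <- cluster_maps(maps, config$smooth_h, config$scc_max_dist_bp)
    write_dense_matrix(cl$scc_matrix, file.path(config$out_dir, "scc_matrix.tsv"))
    write_newick(cl, file.path(config$out_dir, "map_dendrogram.nwk"))
    log$comparison <- list(samples = names(maps))
  }
  write_manifest(file.path(config$out_dir, "manifest.json"), log, config,
                 as.list(pairs_paths))
  invisible(config$out_dir)
}

#' Run the SMLM workflow on localization tables
#'
#' For each named localization CSV (with a matching WKT polygon file):
#' filter on photons/PSF width, group blinking events, assign events to
#' cells, run OPTICS per cell, extract nested macro-/subclusters at the
#' 50/35 nm reachability cuts, and write per-cell assignments and cluster
#' statistics. With exactly two conditions a Kruskal-Wallis comparison
#' report is written.
#'
#' @param config a `run_config`.
#' @param localization_paths named character vector of localization CSVs.
#' @param polygon_paths character vector of WKT files, parallel to
#'   `localization_paths`.
#' @return (invisibly) the output directory.
#' @export
run_smlm <- function(config, localization_paths, polygon_paths) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(names(localization_paths))) {
    names(localization_paths) <- sprintf("cond%d", seq_along(localization_paths))
  }
  missing <- c(localization_paths[!file.exists(localization_paths)],
               polygon_paths[!file.exists(polygon_paths)])
  if (length(missing)) {
    stop("missing input(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stats_tables <- list()
  for (ci in seq_along(localization_paths)) {
    nm <- names(localization_paths)[ci]
    ev <- read_localizations(localization_paths[[ci]])
    polys <- read_polygons_wkt(polygon_paths[[ci]])
    filt <- filter_events(ev, config$photon_min, config$photon_max,
                          config$psf_min, config$psf_max)
    grouped <- group_events(filt, config$group_max_on, config$group_max_off,
                            config$group_radius_nm)
    assigned <- assign_cells(grouped, polys)
    assignments <- list()
    for (cell in sort(unique(assigned$cell_id))) {
      sub <- assigned[assigned$cell_id == cell, , drop = FALSE]
      if (nrow(sub) < config$minpts) next
      ord <- optics(sub, config$minpts, config$epsilon_nm)
      assignments[[as.character(cell)]] <-
        nested_clusters(ord, config$macro_nm, config$sub_nm, config$minpts)
      sub$macro <- assignments[[as.character(cell)]]$macro
      sub$sub <- assignments[[as.character(cell)]]$sub
      utils::write.csv(sub,
                       file.path(config$out_dir,
                                 sprintf("%s_cell%s_assignments.csv", nm, cell)),
                       row.names = FALSE)
    }
    st <- cluster_stats(assignments)
    utils::write.csv(st, file.path(config$out_dir,
                                   sprintf("%s_cluster_stats.csv", nm)),
                     row.names = FALSE)
    stats_tables[[nm]] <- st
    log[[nm]] <- list(
      n_events = nrow(ev), n_filtered = attr(filt, "n_kept"),
      n_molecules = nrow(grouped), n_assigned = nrow(assigned),
      n_cells = length(assignments), n_macroclusters = nrow(st)
    )
  }
  if (length(stats_tables) == 2L) {
    rep_ <- compare_conditions(stats_tables[[1]], stats_tables[[2]],
                               labels = names(stats_tables))
    utils::write.csv(rep_, file.path(config$out_dir, "condition_comparison.csv"),
                     row.names = FALSE)
    log$comparison <- split(rep_, rep_$metric)
  }
  write_manifest(file.path(config$out_dir, "manifest.json"), log, config,
                 c(as.list(localization_paths), as.list(polygon_paths)))
  invisible(config$out_dir)
}
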