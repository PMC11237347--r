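#' Run configuration for the full OFD analysis
#'
#' @param community,hierarchy,traits input file paths, or `NULL` when
#'   `simulate` is given.
#' @param simulate optional `sim_config`; when present the input tables are
#'   generated instead of read.
#' @param run_extents extents to analyse (subset of [extents()]).
#' @param resampling a `resampling_config`.
#' @param k number of dispersal groups to cut the Ward tree at (default 3;
#'   set `NULL` to use the WSS-knee suggestion).
#' @param ward_method Ward variant for clustering.
#' @param n_perm permutations for ANOSIM and the indicator analysis.
#' @param merge_map optional category merge map applied before
#'   standardisation (see [merge_categories()]).
#' @param min_S minimum taxa per fitted curve.
#' @param out_dir output directory for the artifact bundle.
#' @param seed master seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(community = NULL, hierarchy = NULL, traits = NULL,
                       simulate = NULL,
                       run_extents = extents(),
                       resampling = resampling_config(),
                       k = 3L, ward_method = "ward.D2", n_perm = 999L,
                       merge_map = NULL, min_S = 6L,
                       out_dir = "occufreq-run", seed = 1L) {
  stopifnot(all(run_extents %in% extents()))
  if (is.null(simulate)) {
    for (p in c(community, hierarchy, traits))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(community = community, hierarchy = hierarchy,
                 traits = traits, simulate = simulate,
                 run_extents = run_extents, resampling = resampling,
                 k = k, ward_method = ward_method, n_perm = n_perm,
                 merge_map = merge_map, min_S = min_S,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read or simulate the community, hierarchy and trait tables;
#' (2) trait processing — optional category merging, standardisation,
#' imputation, Gower dissimilarity, Ward clustering, ANOSIM verification
#' and multilevel pattern analysis; (3) per requested extent, generation of
#' the SRS ensemble; (4) per-SRS RSOC multimodel inference for every
#' dispersal group; (5) summary table, OFD histograms, and a machine-
#' readable manifest with the seed and all skip/convergence bookkeeping.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results (`groups`,
#'   `anosim`, `indicators`, `per_srs`, `summary`, `histograms`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("occufreq run, seed %d", config$seed))

  # --- stage 1: inputs
  if (!is.null(config$simulate)) {
    traits <- generate_traits(config$simulate)
    community <- generate_community(config$simulate, traits)
  } else {
    hierarchy <- read_hierarchy(config$hierarchy)
    community <- read_community(config$community, hierarchy = hierarchy)
    traits <- read_traits(config$traits)
  }

  # --- stage 2: dispersal groups
  if (!is.null(config$merge_map))
    traits <- merge_categories(traits, config$merge_map)
  std <- standardize_affinities(traits)
  std <- impute_missing(std)
  D <- gower_dissimilarity(std)
  wss <- wss_curve(D, k_max = min(10L, nrow(D) - 1L),
                   method = config$ward_method)
  k <- if (is.null(config$k)) wss$suggested_k else config$k
  groups <- ward_cluster(D, k = k, method = config$ward_method)
  an <- anosim(D, groups, n_perm = config$n_perm, seed = config$seed)
  ind <- multilevel_pattern(std, groups, n_perm = config$n_perm,
                            seed = config$seed)
  log_lines <- c(log_lines,
                 sprintf("dispersal groups: k = %d, ANOSIM R = %.3f (p = %.4g)",
                         k, an$R, an$p))

  # keep only taxa that are both clustered and observed
  labels <- groups$labels[names(groups$labels) %in% community$taxa]

  # --- stages 3-4: ensembles and per-SRS inference
  per_srs <- list()
  histograms <- list()
  for (ext in config$run_extents) {
    ens <- generate_ensemble(community, ext, config$resampling)
    per_srs[[ext]] <- analyze_ensemble(ens, community, groups = labels,
                                       min_S = config$min_S)
    histograms[[ext]] <- ofd_histogram(ens, community, groups = labels)
    log_lines <- c(log_lines, sprintf(
      "%s extent: %d SRSs analysed, %d rejected", ext, length(ens),
      attr(ens, "n_rejected")))
  }
  per_srs <- do.call(rbind, per_srs)
  histograms <- do.call(rbind, histograms)

  # --- stage 5: summaries
  summary_tab <- summarize_ensemble(per_srs)

  paths <- list(
    groups = file.path(config$out_dir, "groups.csv"),
    wss = file.path(config$out_dir, "wss.csv"),
    indicators = file.path(config$out_dir, "indicators.csv"),
    per_srs = file.path(config$out_dir, "per_srs.csv"),
    summary = file.path(config$out_dir, "summary.csv"),
    histograms = file.path(config$out_dir, "histograms.csv"),
    dendrogram = file.path(config$out_dir, "dendrogram.nwk"),
    manifest = file.path(config$out_dir, "manifest.json"),
    log = file.path(config$out_dir, "run.log"))
  write_summary(data.frame(taxon = names(groups$labels),
                           group = unname(groups$labels)), paths$groups)
  write_summary(wss$curve, paths$wss)
  write_summary(ind, paths$indicators)
  write_per_srs(per_srs, paths$per_srs)
  write_summary(summary_tab, paths$summary)
  write_summary(histograms, paths$histograms)
  write_dendrogram(groups, paths$dendrogram)
  jsonlite::write_json(list(
    seed = config$seed, k = k, extents = config$run_extents,
    n_srs = config$resampling$n_srs,
    min_ars_richness = config$resampling$min_ars_richness,
    anosim_R = an$R, anosim_p = an$p,
    n_taxa = length(community$taxa)), paths$manifest,
    auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, paths$log)

  invisible(list(groups = groups, anosim = an, indicators = ind,
                 wss = wss, per_srs = per_srs, summary = summary_tab,
                 histograms = histograms, paths = paths))
}
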