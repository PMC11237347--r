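#' Summarise per-SRS pattern probabilities
#'
#' Reduces the ensemble of per-SRS records to one row per (extent, group):
#' mean Akaike weights of the bimodal, unimodal and random patterns, 95%
#' percentile confidence intervals across SRSs, evidence ratios between
#' pattern pairs computed from the unrounded means, the mean taxa number,
#' and the number of SRSs used.
#'
#' @param records data.frame from [analyze_ensemble()] (possibly several
#'   extents stacked).
#' @param ci_method `"percentile"` (2.5/97.5 percentiles across SRSs,
#'   default) or `"normal"` (mean +/- 1.96 standard errors).
#' @return data.frame, one row per (extent, group), columns
#'   `extent, group, mean_w_bimodal, mean_w_unimodal, mean_w_random`,
#'   `ci_low_*`/`ci_high_*` per pattern, `er_bi_uni, er_uni_bi, er_ra_bi,
#'   er_ra_uni`, `mean_taxa_number`, `n_srs_used`.
#' @export
summarize_ensemble <- function(records,
                               ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  if (is.null(records) || nrow(records) == 0L)
    stop("no per-SRS records to summarise")
  ratio <- function(a, b) if (a == 0) 0 else if (b == 0) Inf else a / b
  ci <- function(v) {
    if (ci_method == "percentile")
      stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    else mean(v) + c(-1.96, 1.96) * stats::sd(v) / sqrt(length(v))
  }
  cells <- split(records, list(records$extent, records$group), drop = TRUE)
  rows <- lapply(cells, function(cc) {
    mb <- mean(cc$w_bimodal); mu <- mean(cc$w_unimodal)
    mr <- mean(cc$w_random)
    cb <- ci(cc$w_bimodal); cu <- ci(cc$w_unimodal); cr <- ci(cc$w_random)
    data.frame(
      extent = cc$extent[1L], group = cc$group[1L],
      mean_w_bimodal = mb, mean_w_unimodal = mu, mean_w_random = mr,
      ci_low_bimodal = cb[1L], ci_high_bimodal = cb[2L],
      ci_low_unimodal = cu[1L], ci_high_unimodal = cu[2L],
      ci_low_random = cr[1L], ci_high_random = cr[2L],
      er_bi_uni = ratio(mb, mu), er_uni_bi = ratio(mu, mb),
      er_ra_bi = ratio(mr, mb), er_ra_uni = ratio(mr, mu),
      mean_taxa_number = mean(cc$S), n_srs_used = nrow(cc),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- order(match(out$extent, extents()), out$group)
  out[ord, , drop = FALSE]
}

#' Mean occupancy-frequency histogram across an ensemble
#'
#' For each SRS (and optionally each dispersal group) every taxon's relative
#' occupancy is binned into left-open, right-closed equal-width classes over
#' `(0, 1]` — by default the five classes (0,0.2], (0.2,0.4], ..., (0.8,1] —
#' and the per-class taxa counts are averaged over the SRSs of the
#' ensemble.
#'
#' @param ensemble list of `srs`.
#' @param community the source `community_data`.
#' @param groups taxon -> group labels, or `NULL` for the pooled assemblage.
#' @param classes number of occupancy classes (default 5).
#' @return data.frame: `extent, group, class_low, class_high, mean_count`.
#' @export
ofd_histogram <- function(ensemble, community, groups = NULL, classes = 5L) {
  if (classes < 2L) stop("need at least 2 occupancy classes")
  if (inherits(groups, "dispersal_groups")) groups <- groups$labels
  breaks <- seq(0, 1, length.out = classes + 1L)
  subsets <- if (is.null(groups)) list(all = NULL) else
    split(names(groups), groups)
  rows <- list()
  for (gname in names(subsets)) {
    counts <- matrix(0, nrow = length(ensemble), ncol = classes)
    for (si in seq_along(ensemble)) {
      r <- occupancies(ensemble[[si]], community,
                       taxa_subset = subsets[[gname]])
      if (!nrow(r)) next
      bin <- findInterval(r$occupancy, breaks, left.open = TRUE,
                          rightmost.closed = TRUE)
      counts[si, ] <- tabulate(bin, nbins = classes)
    }
    rows[[gname]] <- data.frame(
      extent = ensemble[[1L]]$extent, group = gname,
      class_low = breaks[-length(breaks)], class_high = breaks[-1L],
      mean_count = colMeans(counts), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
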