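#' Resampling configuration
#'
#' @param n_srs number of spatially representative samples per extent
#'   (the study design uses 10,000; tests use a few hundred).
#' @param min_ars_richness annually representative samples with fewer taxa
#'   than this are discarded (default 10, since very poor samples do not
#'   give a reliable occupancy pattern).
#' @param max_attempts redraw cap per ARS before it is dropped from its SRS.
#' @param on_exhaust what to do when every redraw of an ARS fails:
#'   `"drop"` shrinks the SRS (with a logged shortfall), `"reject"` rejects
#'   the whole SRS.
#' @param seed master seed; each SRS is drawn from an independent substream
#'   derived from `(seed, extent, srs_index)`, so ensembles are
#'   order-independent and reproducible.
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(n_srs = 10000, min_ars_richness = 10,
                              max_attempts = 100, on_exhaust = c("drop", "reject"),
                              seed = 1L) {
  stopifnot(n_srs >= 1, min_ars_richness >= 0, max_attempts >= 1)
  structure(list(n_srs = as.integer(n_srs),
                 min_ars_richness = as.integer(min_ars_richness),
                 max_attempts = as.integer(max_attempts),
                 on_exhaust = match.arg(on_exhaust),
                 seed = as.integer(seed)),
            class = "resampling_config")
}

#' The four nested spatial extents
#' @return Character vector `reach, subbasin, basin, region`.
#' @export
extents <- function() c("reach", "subbasin", "basin", "region")

#' Draw one annually representative sample (ARS)
#'
#' From one reach's full seasonal sampling, one elementary sample unit is
#' chosen uniformly per season and the four presence sets are pooled, giving
#' a sample representative of an annual period.
#'
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param community a `community_data`.
#' @param reach_id reach to sample from.
#' @return Object of class `ars`: list `taxa` (sorted integer taxon ids),
#'   `reach`, `units` (named integer: chosen unit index per season).
#' @export
draw_ars <- function(community, reach_id) {
  sl <- community$index[[reach_id]]
  if (is.null(sl)) stop("unknown reach: ", reach_id)
  miss <- setdiff(community$seasons, names(sl))
  if (length(miss))
    stop("reach ", reach_id, " has no units for season(s): ",
         paste(miss, collapse = ", "))
  picks <- integer(length(community$seasons))
  taxa <- integer(0)
  for (si in seq_along(community$seasons)) {
    units <- sl[[community$seasons[si]]]
    u <- sample.int(length(units), 1L)
    picks[si] <- as.integer(names(units)[u])
    taxa <- c(taxa, units[[u]])
  }
  structure(list(taxa = sort(unique(taxa)), reach = reach_id,
                 units = stats::setNames(picks, community$seasons)),
            class = "ars")
}

# draw one ARS honouring the richness filter; NULL when attempts exhausted
.draw_ars_filtered <- function(community, reach_id, config) {
  for (att in seq_len(config$max_attempts)) {
    a <- draw_ars(community, reach_id)
    if (length(a$taxa) >= config$min_ars_richness) return(a)
    if (config$min_ars_richness == 0L) return(a)
  }
  NULL
}

# ARS quota per reach for each extent of the default design
.extent_plan <- function(extent, hierarchy) {
  switch(extent,
    reach = {
      r <- sample(hierarchy$reaches, 1L)
      list(block = r, quota = stats::setNames(16L, r))
    },
    subbasin = {
      sb <- sample(names(hierarchy$subbasins), 1L)
      rs <- hierarchy$subbasins[[sb]]
      list(block = sb, quota = stats::setNames(rep(5L, length(rs)), rs))
    },
    basin = {
      b <- sample(names(hierarchy$basins), 1L)
      rs <- hierarchy$basins[[b]]
      list(block = b, quota = stats::setNames(rep(4L, length(rs)), rs))
    },
    region = {
      rs <- hierarchy$reaches
      list(block = "region", quota = stats::setNames(rep(2L, length(rs)), rs))
    },
    stop("unknown extent: ", extent)
  )
}

#' Draw one spatially representative sample (SRS)
#'
#' One spatial block is chosen uniformly for the extent (a reach, one of the
#' two subbasins, one of the two basins, or the whole region) and ARSs are
#' drawn with replacement from its member reaches: 16 from one reach at the
#' reach extent, 5 from each of 3 reaches at the subbasin extent (15 in
#' total, keeping the design balanced), 4 from each of 4 reaches at the
#' basin extent, and 2 from each of the 8 reaches at the regional extent.
#' ARSs below the richness threshold are redrawn from the same reach up to
#' the attempt cap, after which they are dropped (shortfall recorded) or the
#' SRS is rejected, per configuration.
#'
#' @param community a `community_data`.
#' @param extent one of [extents()].
#' @param config a `resampling_config`.
#' @return Object of class `srs`: list `extent`, `block`, `ars` (list of
#'   `ars`), `n_ars`, `shortfall`; or `NULL` if the SRS was rejected.
#' @export
draw_srs <- function(community, extent, config = resampling_config()) {
  plan <- .extent_plan(extent, community$hierarchy)
  ars <- list()
  shortfall <- 0L
  for (r in names(plan$quota)) {
    for (q in seq_len(plan$quota[[r]])) {
      a <- .draw_ars_filtered(community, r, config)
      if (is.null(a)) {
        if (config$on_exhaust == "reject") return(NULL)
        shortfall <- shortfall + 1L
      } else {
        ars[[length(ars) + 1L]] <- a
      }
    }
  }
  if (!length(ars)) return(NULL)
  structure(list(extent = extent, block = plan$block, ars = ars,
                 n_ars = length(ars), shortfall = shortfall),
            class = "srs")
}

#' @export
print.srs <- function(x, ...) {
  cat("srs:", x$extent, "extent, block", x$block, ",", x$n_ars, "ARSs\n")
  invisible(x)
}

# substream seed for SRS i of an extent: deterministic, order-independent,
# kept within 32-bit integer range
.srs_seed <- function(master, extent, i) {
  e <- match(extent, extents())
  as.integer((as.double(master) * 48271 + e * 1299709 + i * 7919) %% 2147483587)
}

#' Generate an ensemble of SRSs
#'
#' Draws `config$n_srs` spatially representative samples at one extent.
#' Each SRS is drawn under a seed derived from `(master seed, extent,
#' index)`, so the i-th SRS does not depend on how many came before it.
#'
#' @param community a `community_data`.
#' @param extent one of [extents()].
#' @param config a `resampling_config`.
#' @return List of `srs` objects (rejected draws are omitted); attribute
#'   `n_rejected` counts rejections.
#' @export
generate_ensemble <- function(community, extent,
                              config = resampling_config()) {
  out <- vector("list", config$n_srs)
  rejected <- 0L
  for (i in seq_len(config$n_srs)) {
    set.seed(.srs_seed(config$seed, extent, i))
    s <- draw_srs(community, extent, config)
    if (is.null(s)) rejected <- rejected + 1L else {
      s$index <- i
      out[[i]] <- s
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  attr(out, "n_rejected") <- rejected
  out
}

#' Provenance log of an ensemble
#'
#' @param ensemble list of `srs` from [generate_ensemble()].
#' @param community the `community_data` the ensemble was drawn from.
#' @return data.frame, one row per ARS: srs index, extent, block, reach,
#'   chosen unit per season, richness.
#' @export
ensemble_provenance <- function(ensemble, community) {
  rows <- lapply(ensemble, function(s) {
    do.call(rbind, lapply(s$ars, function(a) {
      u <- as.list(a$units)
      names(u) <- paste0(names(a$units), "_unit")
      cbind(data.frame(srs_index = s$index, extent = s$extent,
                       block = s$block, reach = a$reach,
                       stringsAsFactors = FALSE),
            as.data.frame(u),
            data.frame(richness = length(a$taxa)))
    }))
  })
  do.call(rbind, rows)
}
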