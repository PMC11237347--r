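#' @keywords internal
"_PACKAGE"

#' Default season labels
#'
#' The study design samples each stream reach once per season; seasons are an
#' ordered categorical with exactly these four labels unless a different set
#' is configured.
#'
#' @return Character vector of the four default season labels.
#' @export
default_seasons <- function() c("spring", "summer", "autumn", "winter")

#' Construct a site hierarchy
#'
#' Maps every stream reach to exactly one subbasin and one basin. Under the
#' default design there are 8 reaches: two subbasins of 3 reaches nested in
#' two basins of 4 reaches, and the region is the union of all reaches.
#'
#' @param df data.frame with columns `reach`, `subbasin`, `basin`.
#' @return An object of class `site_hierarchy`.
#' @export
site_hierarchy <- function(df) {
  need <- c("reach", "subbasin", "basin")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hierarchy is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$reach))
    stop("each reach must appear exactly once in the hierarchy")
  if (anyNA(df$reach) || anyNA(df$basin))
    stop("reach and basin must be non-missing for every row")
  has_sb <- !is.na(df$subbasin)
  structure(list(
    table     = df,
    reaches   = df$reach,
    subbasins = split(df$reach[has_sb], df$subbasin[has_sb]),
    basins    = split(df$reach, df$basin)
  ), class = "site_hierarchy")
}

#' Default 8-reach, 2-subbasin, 2-basin hierarchy
#'
#' Mirrors the nested study design: two subbasins hold 3 reaches each and the
#' two basins each add a fourth reach to a subbasin's three, so the fourth
#' reach of each basin belongs to no subbasin (`NA`).
#'
#' @return A `site_hierarchy`.
#' @export
default_hierarchy <- function() {
  site_hierarchy(data.frame(
    reach    = paste0("R", 1:8),
    subbasin = c("S1", "S1", "S1", NA, "S2", "S2", "S2", NA),
    basin    = c(rep("B1", 4), rep("B2", 4)),
    stringsAsFactors = FALSE
  ))
}

#' Read a reach/subbasin/basin table
#'
#' @param path delimited text file with columns `reach,subbasin,basin`.
#' @param sep field separator (default comma).
#' @return A `site_hierarchy`.
#' @export
read_hierarchy <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  site_hierarchy(df)
}

#' Construct a community data object
#'
#' Holds presence/abundance of taxa in elementary sample units together with
#' the reach/season/unit metadata and the site hierarchy. Abundances are
#' retained for reporting totals only; all downstream computation is on
#' presence/absence.
#'
#' @param long data.frame with columns `reach,season,unit,taxon,abundance`.
#'   Duplicate `(reach, season, unit, taxon)` rows are summed.
#' @param hierarchy a `site_hierarchy` covering every reach in `long`.
#' @param seasons ordered season labels; rows with other labels are an error.
#' @param exclude optional character vector of taxa to drop before analysis.
#' @return An object of class `community_data` with a fast presence index
#'   (`index[[reach]][[season]][[unit]]` = integer taxon ids).
#' @export
community_data <- function(long, hierarchy,
                           seasons = default_seasons(),
                           exclude = NULL) {
  need <- c("reach", "season", "unit", "taxon", "abundance")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("community table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(long) == 0L)
    stop("community table has no rows")
  long$reach <- as.character(long$reach)
  long$season <- as.character(long$season)
  long$taxon <- as.character(long$taxon)
  bad <- setdiff(unique(long$season), seasons)
  if (length(bad))
    stop("unknown season label(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(long$abundance) || any(long$abundance %% 1 != 0) ||
      any(long$abundance < 0) || anyNA(long$abundance))
    stop("abundance must be a non-negative integer")
  if (!is.numeric(long$unit) || any(long$unit %% 1 != 0) || any(long$unit < 1))
    stop("unit must be a positive integer index")
  unk <- setdiff(unique(long$reach), hierarchy$reaches)
  if (length(unk))
    stop("reach(es) absent from hierarchy: ", paste(unk, collapse = ", "))
  if (!is.null(exclude))
    long <- long[!(long$taxon %in% exclude), , drop = FALSE]
  if (nrow(long) == 0L)
    stop("no rows left after exclusions")

  # sum duplicates
  key <- paste(long$reach, long$season, long$unit, long$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    ab <- tapply(long$abundance, key, sum)
    parts <- strsplit(names(ab), "\r", fixed = TRUE)
    long <- data.frame(
      reach = vapply(parts, `[`, "", 1L),
      season = vapply(parts, `[`, "", 2L),
      unit = as.integer(vapply(parts, `[`, "", 3L)),
      taxon = vapply(parts, `[`, "", 4L),
      abundance = as.integer(ab),
      stringsAsFactors = FALSE
    )
  }

  taxa <- sort(unique(long$taxon))
  tid <- match(long$taxon, taxa)
  present <- long$abundance > 0

  # nested presence index: reach -> season -> unit -> integer taxon ids
  index <- list()
  units_per <- list()
  for (r in sort(unique(long$reach))) {
    index[[r]] <- list()
    lr <- long$reach == r
    for (s in seasons) {
      sel <- lr & long$season == s
      if (!any(sel)) next
      us <- sort(unique(long$unit[sel]))
      index[[r]][[s]] <- lapply(us, function(u) {
        sort(unique(tid[sel & long$unit == u & present]))
      })
      names(index[[r]][[s]]) <- as.character(us)
      units_per[[paste(r, s)]] <- length(us)
    }
  }

  structure(list(
    long      = long,
    taxa      = taxa,
    index     = index,
    seasons   = seasons,
    hierarchy = hierarchy,
    n_units   = unlist(units_per)
  ), class = "community_data")
}

#' @export
print.community_data <- function(x, ...) {
  cat("community_data:", length(x$taxa), "taxa,",
      length(x$index), "reaches,", length(x$seasons), "seasons,",
      sum(x$n_units), "sample units\n")
  invisible(x)
}

#' Read a long-format community table
#'
#' @param path delimited text with columns `reach,season,unit,taxon,abundance`.
#' @param hierarchy a `site_hierarchy`; if `NULL`, a trivial hierarchy with
#'   one subbasin and basin per reach is fabricated (useful for ad-hoc data).
#' @param seasons ordered season labels.
#' @param sep field separator.
#' @param exclude optional taxa to drop.
#' @return A `community_data`.
#' @export
read_community <- function(path, hierarchy = NULL,
                           seasons = default_seasons(), sep = ",",
                           exclude = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("community file is empty: ", path)
  if (is.null(hierarchy)) {
    rs <- sort(unique(as.character(df$reach)))
    hierarchy <- site_hierarchy(data.frame(
      reach = rs, subbasin = rs, basin = rs, stringsAsFactors = FALSE))
  }
  community_data(df, hierarchy, seasons = seasons, exclude = exclude)
}

#' Convert a wide taxa matrix to the long community layout
#'
#' @param df data.frame with columns `reach,season,unit` followed by one
#'   column per taxon holding abundances.
#' @return Long data.frame with `reach,season,unit,taxon,abundance`, zero
#'   abundances dropped.
#' @export
community_wide_to_long <- function(df) {
  meta <- c("reach", "season", "unit")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stop("wide table is missing column(s): ", paste(miss, collapse = ", "))
  taxa <- setdiff(names(df), meta)
  out <- do.call(rbind, lapply(taxa, function(tx) {
    data.frame(reach = df$reach, season = df$season, unit = df$unit,
               taxon = tx, abundance = df[[tx]], stringsAsFactors = FALSE)
  }))
  out[out$abundance > 0, , drop = FALSE]
}

#' Construct a fuzzy-coded trait matrix
#'
#' Taxa-by-category affinities with a category-to-trait map and taxonomy for
#' imputation. Raw fuzzy codes express no (0), weak (1), moderate (2) or
#' strong (3) affinity with a trait category; after [standardize_affinities()]
#' the categories of each trait are proportions summing to 1 (or the whole
#' trait is `NA`, meaning missing).
#'
#' @param affinity numeric matrix, rows = taxa (rownames required),
#'   columns = trait categories named `trait.category`.
#' @param taxonomy data.frame with columns `taxon,genus,family,superfamily`.
#' @param trait_of optional named character vector category -> trait; derived
#'   from the dotted column names when `NULL`.
#' @param standardized logical; `TRUE` once affinities are proportions.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(affinity, taxonomy, trait_of = NULL,
                         standardized = FALSE) {
  affinity <- as.matrix(affinity)
  if (is.null(rownames(affinity)))
    stop("affinity matrix needs taxon rownames")
  if (is.null(trait_of)) {
    trait_of <- sub("\\..*$", "", colnames(affinity))
    names(trait_of) <- colnames(affinity)
  }
  if (!standardized) {
    vals <- affinity[!is.na(affinity)]
    if (!all(vals %in% 0:3))
      stop("raw fuzzy codes must lie in {0, 1, 2, 3}")
  }
  taxonomy$taxon <- as.character(taxonomy$taxon)
  if (!all(rownames(affinity) %in% taxonomy$taxon))
    stop("every taxon in the affinity matrix needs a taxonomy row")
  taxonomy <- taxonomy[match(rownames(affinity), taxonomy$taxon), ,
                       drop = FALSE]
  structure(list(
    affinity = affinity,
    taxonomy = taxonomy,
    trait_of = trait_of,
    standardized = standardized
  ), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x$affinity), "taxa x", ncol(x$affinity),
      "categories (", length(unique(x$trait_of)), "traits),",
      if (x$standardized) "standardized" else "raw fuzzy codes", "\n")
  invisible(x)
}

#' Read a fuzzy-coded trait table
#'
#' Expected columns: `taxon,genus,family,superfamily` then one column per
#' trait category with dotted `trait.category` headers holding raw fuzzy
#' codes in `{0,1,2,3}`. Blank cells become missing markers (`NA`), never
#' zero, and survive untouched until imputation.
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @return A `trait_matrix` with raw codes.
#' @export
read_traits <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("taxon", "genus", "family", "superfamily")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "))
  cats <- setdiff(names(df), need)
  if (!length(cats)) stop("trait table has no trait-category columns")
  aff <- as.matrix(df[, cats, drop = FALSE])
  mode(aff) <- "numeric"
  rownames(aff) <- df$taxon
  bad <- aff[!is.na(aff)]
  if (!all(bad %in% 0:3))
    stop("raw fuzzy codes outside {0,1,2,3} in ", path)
  trait_matrix(aff, df[, need], standardized = FALSE)
}

#' Write a results table as delimited text
#'
#' Numeric columns are written at 6 significant digits so the file
#' round-trips losslessly at that precision; column order is preserved.
#'
#' @param table data.frame of results.
#' @param path output file.
#' @param sep field separator.
#' @return Invisibly, the path.
#' @export
write_summary <- function(table, path, sep = ",") {
  if (is.null(table) || nrow(table) == 0L) {
    warning("writing header-only results file: ", path)
  }
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @param records per-SRS records data.frame (one row per SRS-group cell).
#' @export
write_per_srs <- function(records, path, sep = ",") {
  write_summary(records, path, sep = sep)
}
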