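#' Merge trait categories by the maximum-affinity rule
#'
#' Wide fuzzy-coded traits (body size, female wing length) carry many narrow
#' categories; merging them into broader categories keeps results
#' interpretable. The merged category receives the highest raw affinity among
#' its members. Merging happens on raw codes, before standardisation.
#'
#' @param traits a raw (non-standardized) `trait_matrix`.
#' @param merge_map named list: new `trait.category` name -> character vector
#'   of existing category columns of the same parent trait.
#' @return A `trait_matrix` with the merged columns replacing their members.
#' @export
merge_categories <- function(traits, merge_map) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (traits$standardized)
    stop("merge categories on raw codes, before standardization")
  aff <- traits$affinity
  trait_of <- traits$trait_of
  for (new in names(merge_map)) {
    old <- merge_map[[new]]
    if (!all(old %in% colnames(aff)))
      stop("unknown categories in merge map: ",
           paste(setdiff(old, colnames(aff)), collapse = ", "))
    parents <- unique(trait_of[old])
    if (length(parents) != 1L)
      stop("cannot merge categories across traits: ",
           paste(parents, collapse = ", "))
    block <- aff[, old, drop = FALSE]
    merged <- apply(block, 1L, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    keep <- setdiff(colnames(aff), old)
    aff <- cbind(aff[, keep, drop = FALSE], merged)
    colnames(aff)[ncol(aff)] <- new
    trait_of <- c(trait_of[keep], stats::setNames(parents, new))
  }
  trait_matrix(aff, traits$taxonomy, trait_of = trait_of,
               standardized = FALSE)
}

#' Standardise fuzzy codes to within-trait proportions
#'
#' For each taxon and trait, each category affinity is divided by the sum of
#' raw codes over that trait's categories, so the categories describe
#' relative trait occurrence and sum to 1. A trait whose codes sum to zero,
#' or that contains a missing cell, is flagged missing (`NA` across all of
#' its categories) for that taxon and is left for [impute_missing()].
#'
#' @param traits a raw `trait_matrix`.
#' @return A standardized `trait_matrix`.
#' @export
standardize_affinities <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (traits$standardized) return(traits)
  aff <- traits$affinity
  out <- aff
  for (tr in unique(traits$trait_of)) {
    cols <- names(traits$trait_of)[traits$trait_of == tr]
    block <- aff[, cols, drop = FALSE]
    s <- rowSums(block)                      # NA if any member missing
    bad <- is.na(s) | s == 0
    norm <- block / s
    norm[bad, ] <- NA_real_
    out[, cols] <- norm
  }
  trait_matrix(out, traits$taxonomy, trait_of = traits$trait_of,
               standardized = TRUE)
}

#' Impute missing traits from taxonomic relatives
#'
#' Missing standardized traits are replaced by the mean profile of taxa
#' sharing the lowest available higher taxonomic rank: family first, then
#' superfamily. The imputed profile is re-normalised to sum 1. Taxa that
#' still miss a trait after the ladder are dropped with a warning (they
#' cannot take part in clustering).
#'
#' @param traits a standardized `trait_matrix`.
#' @param level_order taxonomy ranks to try, in order.
#' @return A standardized `trait_matrix` with no missing cells.
#' @export
impute_missing <- function(traits, level_order = c("family", "superfamily")) {
  stopifnot(inherits(traits, "trait_matrix"), traits$standardized)
  aff <- traits$affinity
  tax <- traits$taxonomy
  traits_list <- unique(traits$trait_of)
  for (tr in traits_list) {
    cols <- names(traits$trait_of)[traits$trait_of == tr]
    missing_rows <- which(is.na(aff[, cols[1L]]))
    for (i in missing_rows) {
      for (lev in level_order) {
        mates <- which(tax[[lev]] == tax[[lev]][i])
        mates <- setdiff(mates, i)
        mates <- mates[!is.na(aff[mates, cols[1L]])]
        if (length(mates)) {
          prof <- colMeans(aff[mates, cols, drop = FALSE])
          aff[i, cols] <- prof / sum(prof)
          break
        }
      }
    }
  }
  still <- rowSums(is.na(aff)) > 0
  if (any(still)) {
    warning("no taxonomic donors for ", sum(still), " taxon/taxa (",
            paste(utils::head(rownames(aff)[still], 5), collapse = ", "),
            if (sum(still) > 5) ", ..." else "",
            "); excluded from the trait matrix")
    aff <- aff[!still, , drop = FALSE]
    tax <- tax[!still, , drop = FALSE]
  }
  trait_matrix(aff, tax, trait_of = traits$trait_of, standardized = TRUE)
}

#' Gower dissimilarity between taxa
#'
#' Mean of range-normalised absolute differences over trait categories,
#' computed per pair over the categories that are non-missing in both taxa.
#' Categories with zero observed range contribute nothing (they are excluded
#' from the per-pair mean).
#'
#' @param traits a standardized `trait_matrix`, or a plain numeric matrix of
#'   variables in any range (rows = taxa).
#' @return Symmetric taxa-by-taxa matrix of dissimilarities in `[0, 1]`,
#'   zero diagonal.
#' @export
gower_dissimilarity <- function(traits) {
  x <- if (inherits(traits, "trait_matrix")) traits$affinity else as.matrix(traits)
  n <- nrow(x)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (v in seq_len(ncol(x))) {
    col <- x[, v]
    rng <- diff(range(col, na.rm = TRUE))
    ok <- !is.na(col)
    both <- outer(ok, ok, `&`)
    if (!is.finite(rng) || rng == 0) next   # zero-range variable: no signal
    d <- abs(outer(col, col, `-`)) / rng
    d[!both] <- 0
    num <- num + d
    den <- den + both
  }
  out <- num / den
  out[den == 0] <- NA_real_
  diag(out) <- 0
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's criterion (the `ward.D2` variant,
#' which squares the dissimilarities internally) cut at `k` groups. The
#' merge order of `stats::hclust` is deterministic for a given matrix; ties
#' in merge cost are resolved by the candidate with the smaller index.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param k number of groups, `2 <= k <= n - 1` (`k = n` is allowed and
#'   yields singletons).
#' @param method linkage passed to [stats::hclust()]; `"ward.D2"` default.
#' @return An object of class `dispersal_groups`: list with `labels` (named
#'   character vector taxon -> `"DG<i>"`), `k`, and the `hclust` tree.
#' @export
ward_cluster <- function(D, k, method = "ward.D2") {
  d <- stats::as.dist(D)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must lie in 1..n")
  hc <- stats::hclust(d, method = method)
  memb <- stats::cutree(hc, k = k)
  labels <- stats::setNames(paste0("DG", memb), names(memb))
  structure(list(labels = labels, k = k, tree = hc, method = method),
            class = "dispersal_groups")
}

#' @export
print.dispersal_groups <- function(x, ...) {
  cat("dispersal_groups: k =", x$k, "(", x$method, ")\n")
  print(table(x$labels))
  invisible(x)
}

#' Export a clustering tree as Newick text
#'
#' @param groups a `dispersal_groups` (or an `hclust`).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_dendrogram <- function(groups, path) {
  hc <- if (inherits(groups, "dispersal_groups")) groups$tree else groups
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Within-cluster sum of squares across cluster numbers
#'
#' For each `k`, memberships are taken from the Ward tree and the total WSS
#' is computed on the dissimilarity representation as
#' `sum over clusters of sum_{i<j in C} d_ij^2 / |C|`. A knee is suggested
#' as the `k` maximising the second forward difference of the WSS curve
#' (the sharpest bend); the choice can be overridden downstream.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k_max largest cluster number to evaluate.
#' @param method Ward variant for the underlying tree.
#' @return Object of class `wss_curve`: data.frame `k, wss` plus
#'   `suggested_k`.
#' @export
wss_curve <- function(D, k_max, method = "ward.D2") {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k_max > n) stop("k_max must be <= number of taxa")
  hc <- stats::hclust(stats::as.dist(D), method = method)
  D2 <- D^2
  wss_of <- function(memb) {
    sum(vapply(split(seq_len(n), memb), function(idx) {
      if (length(idx) < 2L) return(0)
      sum(D2[idx, idx]) / (2 * length(idx))
    }, 0))
  }
  ks <- seq_len(k_max)
  wss <- vapply(ks, function(k) wss_of(stats::cutree(hc, k)), 0)
  suggested <- if (k_max >= 3) {
    d2 <- wss[3:k_max] - 2 * wss[2:(k_max - 1)] + wss[1:(k_max - 2)]
    ks[which.max(d2) + 1L]
  } else NA_integer_
  structure(list(curve = data.frame(k = ks, wss = wss),
                 suggested_k = suggested),
            class = "wss_curve")
}

# R statistic on precomputed pair ranks; g is the label vector
.anosim_stat <- function(rk, i, j, g) {
  within <- g[i] == g[j]
  (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. `R = (mean rank between - mean rank within) /
#' (M / 2)` with `M = n(n-1)/2`; the p-value uses the add-one permutation
#' estimator `p = (1 + #\{R* >= R\}) / (1 + n_perm)`.
#'
#' @param D symmetric dissimilarity matrix.
#' @param groups vector of group labels (length `n`), or a
#'   `dispersal_groups`.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional RNG seed for the permutations.
#' @return Object of class `anosim_result`: list `R`, `p`, `n_perm`,
#'   `perm_R` (the null statistics).
#' @export
anosim <- function(D, groups, n_perm = 999, seed = NULL) {
  if (inherits(groups, "dispersal_groups")) groups <- groups$labels
  D <- as.matrix(D)
  n <- nrow(D)
  g <- as.character(groups)
  if (length(g) != n) stop("groups must have one label per taxon")
  if (length(unique(g)) < 2L) stop("ANOSIM needs at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least two members")
  low <- which(lower.tri(D), arr.ind = TRUE)
  i <- low[, 1L]; j <- low[, 2L]
  rk <- rank(D[low])
  obs <- .anosim_stat(rk, i, j, g)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(p) .anosim_stat(rk, i, j, sample(g)), 0)
  structure(list(R = obs,
                 p = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_perm = n_perm, perm_R = perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  invisible(x)
}

# all non-empty proper subsets of group labels, as a list of character vectors
.group_combinations <- function(levels) {
  n <- length(levels)
  combos <- list()
  for (size in seq_len(n - 1L)) {
    cs <- utils::combn(levels, size, simplify = FALSE)
    combos <- c(combos, cs)
  }
  combos
}

#' Multilevel pattern analysis of trait categories
#'
#' Indicator analysis associating each trait category with the dispersal
#' group combination it marks best. For every non-empty proper subset of
#' groups, the point-biserial association `r_pb` is the Pearson correlation
#' between the category's affinity vector and the 0/1 membership vector of
#' the subset; the best subset is reported with a permutation p-value
#' (group labels permuted, best-subset statistic recomputed, add-one
#' estimator). A constant affinity vector has undefined `r_pb` and is
#' reported as 0 with `degenerate = TRUE`.
#'
#' @param traits standardized (and imputed) `trait_matrix`.
#' @param groups group labels per taxon, or a `dispersal_groups`.
#' @param n_perm number of permutations (default 999).
#' @param seed optional RNG seed.
#' @return data.frame: `category, combination, r_pb, p, degenerate`.
#' @export
multilevel_pattern <- function(traits, groups, n_perm = 999, seed = NULL) {
  stopifnot(inherits(traits, "trait_matrix"))
  if (inherits(groups, "dispersal_groups")) groups <- groups$labels
  x <- traits$affinity
  g <- as.character(groups[rownames(x)])
  if (anyNA(g)) stop("every taxon in the trait matrix needs a group label")
  levs <- sort(unique(g))
  if (length(levs) < 2L) stop("need at least two groups")
  combos <- .group_combinations(levs)
  memb <- vapply(combos, function(cc) as.numeric(g %in% cc),
                 numeric(length(g)))   # n x n_combos

  best_of <- function(v) {
    if (stats::sd(v) == 0) return(c(NA_integer_, 0))
    r <- suppressWarnings(stats::cor(v, memb))
    r[is.na(r)] <- -Inf
    b <- which.max(r)
    c(b, r[b])
  }

  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_perm, sample(length(g)))

  out <- lapply(seq_len(ncol(x)), function(ci) {
    v <- x[, ci]
    ob <- best_of(v)
    if (is.na(ob[1L])) {
      return(data.frame(category = colnames(x)[ci], combination = NA,
                        r_pb = 0, p = NA_real_, degenerate = TRUE))
    }
    null_r <- vapply(seq_len(n_perm),
                     function(p) best_of(v[perms[, p]])[2L], 0)
    data.frame(category = colnames(x)[ci],
               combination = paste(combos[[ob[1L]]], collapse = "+"),
               r_pb = ob[2L],
               p = (1 + sum(null_r >= ob[2L])) / (1 + n_perm),
               degenerate = FALSE)
  })
  do.call(rbind, out)
}
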