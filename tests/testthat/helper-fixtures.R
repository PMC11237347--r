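# Shared fixtures and independent oracles, built in code at test time.

# A tiny deterministic community: nr reaches, 4 seasons, nu units each.
# Taxon presence is seeded so fixtures are stable across runs.
make_toy_community <- function(nr = 8, nu = 5, n_taxa = 30, seed = 42,
                               p = 0.35) {
  set.seed(seed)
  seasons <- default_seasons()
  taxa <- sprintf("sp%02d", seq_len(n_taxa))
  rows <- list()
  for (r in paste0("R", seq_len(nr))) for (s in seasons) for (u in seq_len(nu)) {
    pres <- taxa[runif(n_taxa) < p]
    if (!length(pres)) pres <- taxa[1]
    rows[[length(rows) + 1]] <- data.frame(
      reach = r, season = s, unit = u, taxon = pres,
      abundance = 1 + rpois(length(pres), 2), stringsAsFactors = FALSE)
  }
  h <- if (nr == 8) default_hierarchy() else {
    rs <- paste0("R", seq_len(nr))
    site_hierarchy(data.frame(reach = rs, subbasin = rs, basin = rs))
  }
  community_data(do.call(rbind, rows), h)
}

# Small raw trait table covering two traits with taxonomy for imputation.
make_toy_traits <- function() {
  aff <- rbind(
    t1 = c(0, 1, 3, 2, 0),
    t2 = c(2, 2, 0, 0, 3),
    t3 = c(3, 0, 0, 1, 1),
    t4 = c(NA, NA, 2, 1, 0),  # trait A missing
    t5 = c(1, 0, 3, NA, NA))  # trait B missing
  colnames(aff) <- c("A.x", "A.y", "B.x", "B.y", "B.z")
  taxonomy <- data.frame(
    taxon = rownames(aff),
    genus = paste0("g", 1:5),
    family = c("f1", "f1", "f2", "f1", "f2"),
    superfamily = c("sf1", "sf1", "sf1", "sf1", "sf1"),
    stringsAsFactors = FALSE)
  trait_matrix(aff, taxonomy)
}

# Brute-force Gower: double loop over pairs and variables.
gower_brute <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v, na.rm = TRUE)))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; cnt <- 0
    for (v in seq_len(ncol(x))) {
      if (is.na(x[i, v]) || is.na(x[j, v]) || rng[v] == 0) next
      num <- num + abs(x[i, v] - x[j, v]) / rng[v]
      cnt <- cnt + 1
    }
    out[i, j] <- if (cnt > 0) num / cnt else NA_real_
  }
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

# Brute-force ANOSIM R from first principles (explicit rank bookkeeping).
anosim_R_brute <- function(D, g) {
  n <- nrow(D)
  d <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, D[i, j]); within <- c(within, g[i] == g[j])
  }
  rk <- rank(d)
  (mean(rk[!within]) - mean(rk[within])) / (length(d) / 2)
}

# Brute-force best indicator subset: explicit loops, hand-rolled correlation.
indicator_brute <- function(v, g) {
  levs <- sort(unique(g))
  best_r <- -Inf; best <- NULL
  for (size in seq_len(length(levs) - 1)) {
    for (cc in utils::combn(levs, size, simplify = FALSE)) {
      m <- as.numeric(g %in% cc)
      num <- sum((v - mean(v)) * (m - mean(m)))
      den <- sqrt(sum((v - mean(v))^2) * sum((m - mean(m))^2))
      r <- num / den
      if (r > best_r) { best_r <- r; best <- cc }
    }
  }
  list(r = best_r, combination = paste(best, collapse = "+"))
}

# Refining grid search for the exponential-concave model: an independent
# least-squares oracle that never calls the package's fitter.
grid_fit_exp_concave <- function(R, O, lo = c(-0.5, 0, 0.01),
                                 hi = c(0.5, 2, 1), steps = 12, rounds = 4) {
  rss_of <- function(p) sum((O - (p[1] + p[2] * exp(-p[3] * R)))^2)
  best <- NULL; best_rss <- Inf
  for (round in seq_len(rounds)) {
    grid <- expand.grid(
      y0 = seq(lo[1], hi[1], length.out = steps),
      a = seq(lo[2], hi[2], length.out = steps),
      b = seq(lo[3], hi[3], length.out = steps))
    rss <- apply(grid, 1, rss_of)
    i <- which.min(rss)
    if (rss[i] < best_rss) { best_rss <- rss[i]; best <- as.numeric(grid[i, ]) }
    span <- (hi - lo) / steps
    lo <- pmax(best - 2 * span, c(-1, 0, 1e-4))
    hi <- best + 2 * span
  }
  list(params = c(y0 = best[1], a = best[2], b = best[3]), rss = best_rss)
}

# Noisy RSOC generated from a named model's curve (used for recovery tests).
make_model_rsoc <- function(model, S = 25, sd = 0.01) {
  R <- seq_len(S)
  mu <- switch(model,
    exp_concave = 0.05 + 0.9 * exp(-0.25 * R),
    power_exp = 1.0 * R^0.15 * exp(-0.1 * R),
    sig_symmetric = 1 / (1 + exp(0.3 * R - 5)),
    sig_asymmetric = 1 * (1 - exp(-20 * R^(-1))),
    linear = 0.9 - 0.03 * R)
  data.frame(rank = R, occupancy = pmin(pmax(mu + rnorm(S, 0, sd), 1e-4), 1))
}
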