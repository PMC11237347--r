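# Minimal hand-built SRS: taxa ids are indices into `community$taxa`.
fake_srs <- function(ars_taxa, extent = "reach") {
  structure(list(extent = extent, block = "R1",
                 ars = lapply(ars_taxa, function(tx)
                   structure(list(taxa = sort(tx), reach = "R1",
                                  units = c(spring = 1L, summer = 1L,
                                            autumn = 1L, winter = 1L)),
                             class = "ars")),
                 n_ars = length(ars_taxa), shortfall = 0L, index = 1L),
            class = "srs")
}

fake_community <- function(n_taxa) {
  structure(list(taxa = sprintf("sp%02d", seq_len(n_taxa))),
            class = "community_data")
}

test_that("relative occupancy is the ARS count over the ARS total, ranked
           descending with identifier tie-breaks", {
  cd <- fake_community(4)
  srs <- fake_srs(c(rep(list(1:2), 4), rep(list(2:3), 12)))
  r <- occupancies(srs, cd)
  expect_equal(attr(r, "n_ars"), 16)
  # sp02 in all 16 ARSs -> O = 1, rank 1; sp01 in 4 of 16 -> O = 0.25
  expect_equal(r$occupancy[r$taxon == "sp02"], 1)
  expect_equal(r$rank[r$taxon == "sp02"], 1)
  expect_equal(r$occupancy[r$taxon == "sp01"], 0.25)
  # sp04 absent everywhere is excluded
  expect_false("sp04" %in% r$taxon)
  expect_true(all(diff(r$occupancy) <= 0))

  # equal occupancies are ordered by taxon identifier
  tie <- occupancies(fake_srs(list(c(1, 3), c(1, 3))), cd)
  expect_equal(tie$taxon, c("sp01", "sp03"))

  # subsetting to a group restricts the curve
  sub <- occupancies(srs, cd, taxa_subset = c("sp01", "sp04"))
  expect_equal(sub$taxon, "sp01")
})

test_that("an exact linear curve is recovered with near-zero residue", {
  R <- 1:16
  rsoc <- data.frame(rank = R, occupancy = -0.05 * R + 0.9)
  f <- fit_model(rsoc, "linear")
  expect_true(f$converged)
  expect_equal(unname(f$params["a"]), -0.05, tolerance = 1e-10)
  expect_equal(unname(f$params["b"]), 0.9, tolerance = 1e-10)
  expect_lt(f$rss, 1e-20)
})

test_that("exponential-concave fits agree with an independent grid oracle", {
  set.seed(17)
  R <- 1:30
  O <- 0.05 + 0.9 * exp(-0.25 * R) + rnorm(30, 0, 0.01)
  rsoc <- data.frame(rank = R, occupancy = O)
  f <- fit_model(rsoc, "exp_concave")
  expect_true(f$converged)
  oracle <- grid_fit_exp_concave(R, O)
  # the damped-least-squares optimum is at least as good as the refined
  # grid's, and the parameter estimates agree closely
  expect_lte(f$rss, oracle$rss + 1e-8)
  expect_equal(unname(f$params), unname(oracle$params), tolerance = 0.05)
  expect_equal(unname(f$params), c(0.05, 0.9, 0.25), tolerance = 0.1)
})

test_that("curves too short for the AICc correction are not fitted", {
  rsoc <- data.frame(rank = 1:4, occupancy = c(0.9, 0.5, 0.3, 0.2))
  f <- fit_model(rsoc, "exp_concave")
  expect_false(f$converged)
})

test_that("AICc equals the closed form, grows with RSS, and floors
           degenerate fits", {
  expect_equal(aicc(0.04, 16, 3), 16 * log(0.0025) + 6 + 2)
  expect_gt(aicc(0.08, 16, 3), aicc(0.04, 16, 3))
  expect_error(aicc(0.1, 4, 3), "n > k")
  # rss below the floor is clamped: equal scores for any sub-floor rss
  expect_equal(aicc(1e-30, 16, 3), aicc(1e-13, 16, 3))
})

test_that("Akaike weights normalise, shift-invariantly, over converged fits", {
  mk <- function(aicc, converged = TRUE)
    structure(list(model = "m", aicc = aicc, converged = converged,
                   n = 20, k = 4), class = "rsoc_fit")
  fits <- list(a = mk(10), b = mk(10), c = mk(10), d = mk(10), e = mk(10))
  w <- vapply(akaike_weights(fits), `[[`, 0, "weight")
  expect_equal(unname(w), rep(0.2, 5))

  # delta = (0, 2): w = 1/(1 + e^-1), e^-1/(1 + e^-1)
  fits2 <- list(a = mk(100), b = mk(102))
  w2 <- vapply(akaike_weights(fits2), `[[`, 0, "weight")
  expect_equal(unname(w2), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # shifting every AICc by a constant leaves weights unchanged
  w3 <- vapply(akaike_weights(list(a = mk(-40), b = mk(-38))), `[[`, 0,
               "weight")
  expect_equal(w3, w2)
  # non-converged fits get zero weight; all-failed errors out
  w4 <- vapply(akaike_weights(list(a = mk(10), b = mk(5, FALSE))), `[[`, 0,
               "weight")
  expect_equal(unname(w4), c(1, 0))
  expect_error(akaike_weights(list(a = mk(1, FALSE))), "no converged")
})

test_that("pattern probabilities follow the family rule and the sign of the
           power-exponential exponent", {
  mk_fit <- function(model, w, params = NULL)
    structure(list(model = model, weight = w, params = params, n = 25,
                   converged = TRUE), class = "rsoc_fit")
  fits <- list(
    exp_concave = mk_fit("exp_concave", 0.3),
    power_exp = mk_fit("power_exp", 0.3, c(a = 1, b = 0.5, c = 0.1)),
    sig_symmetric = mk_fit("sig_symmetric", 0.2),
    sig_asymmetric = mk_fit("sig_asymmetric", 0.1),
    linear = mk_fit("linear", 0.1))
  p <- classify_patterns(fits)
  expect_equal(c(p$w_bimodal, p$w_unimodal, p$w_random), c(0.6, 0.3, 0.1))

  fits$power_exp$params["b"] <- -0.5
  p2 <- classify_patterns(fits)
  expect_equal(c(p2$w_bimodal, p2$w_unimodal, p2$w_random), c(0.3, 0.6, 0.1))

  # all weight on the linear model -> pure random pattern
  fits3 <- lapply(fits, function(f) { f$weight <- 0; f })
  fits3$linear$weight <- 1
  p3 <- classify_patterns(fits3)
  expect_equal(c(p3$w_bimodal, p3$w_unimodal, p3$w_random), c(0, 0, 1))

  # a non-converged power-exponential contributes nothing
  fits4 <- fits
  fits4$power_exp$converged <- FALSE
  fits4$power_exp$weight <- 0
  p4 <- classify_patterns(fits4)
  expect_true(is.na(p4$b_hat_powexp))
  expect_equal(p4$w_bimodal, 0.3)
})

test_that("per-SRS analysis conserves taxa across groups, sums pattern
           probabilities to one, and is deterministic", {
  cd <- make_toy_community(nr = 8, nu = 6, n_taxa = 40, seed = 3)
  set.seed(8)
  srs <- draw_srs(cd, "region", resampling_config(min_ars_richness = 0))
  groups <- setNames(rep(c("DG1", "DG2"), each = 20), cd$taxa)
  rec <- analyze_srs(srs, cd, groups)
  pooled <- analyze_srs(srs, cd, NULL)
  expect_equal(sum(rec$S), pooled$S)
  expect_equal(rec$w_bimodal + rec$w_unimodal + rec$w_random,
               rep(1, nrow(rec)), tolerance = 1e-9)
  rec2 <- analyze_srs(srs, cd, groups)
  expect_identical(rec, rec2)
})

test_that("a linear assemblage is classified random for every group", {
  # build an SRS whose every group RSOC is exactly linear in occupancy
  cd <- fake_community(24)
  n_ars <- 24
  # taxon j of each 12-taxon group occurs in the first (25 - j) ARSs, so
  # occupancy declines exactly linearly with rank in both groups
  ars_taxa <- lapply(seq_len(n_ars), function(k) {
    g1 <- which(25 - seq_len(12) >= k)
    g2 <- 12 + which(25 - seq_len(12) >= k)
    c(g1, g2)
  })
  srs <- fake_srs(ars_taxa)
  groups <- setNames(rep(c("DG1", "DG2"), each = 12), cd$taxa)
  rec <- analyze_srs(srs, cd, groups)
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$w_random > 0.95))
})
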