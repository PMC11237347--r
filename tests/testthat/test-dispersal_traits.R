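test_that("category merging takes the maximum raw affinity", {
  aff <- rbind(t1 = c(1, 3, 0, 2), t2 = c(0, 0, 0, 1))
  colnames(aff) <- c("A.a1", "A.a2", "A.a3", "B.b1")
  tax <- data.frame(taxon = c("t1", "t2"), genus = c("g1", "g2"),
                    family = "f1", superfamily = "sf1")
  tm <- trait_matrix(aff, tax)
  merged <- merge_categories(tm, list(A.wide = c("A.a1", "A.a2", "A.a3")))
  expect_equal(unname(merged$affinity[, "A.wide"]), c(3, 0))
  expect_equal(merged$affinity[, "B.b1"], aff[, "B.b1"])

  # singleton merge is the identity; cross-trait merges are refused
  single <- merge_categories(tm, list(B.only = "B.b1"))
  expect_equal(unname(single$affinity[, "B.only"]), c(2, 1))
  expect_error(merge_categories(tm, list(bad = c("A.a1", "B.b1"))),
               "across traits")
})

test_that("standardisation yields within-trait proportions or missing flags", {
  tm <- make_toy_traits()
  std <- standardize_affinities(tm)
  # (0,1) over trait A -> (0, 1); (3,1,1) over B -> (0.6, 0.2, 0.2)
  expect_equal(unname(std$affinity["t1", c("A.x", "A.y")]), c(0, 0.25) / 0.25)
  expect_equal(unname(std$affinity["t3", c("B.x", "B.y", "B.z")]),
               c(0, 0.5, 0.5))
  expect_equal(unname(std$affinity["t1", c("B.x", "B.y", "B.z")]),
               c(0.6, 0.4, 0) / 1)
  # all-zero trait and blank cells both flag the trait missing
  zero_aff <- rbind(z = c(0, 0, 2))
  colnames(zero_aff) <- c("A.x", "A.y", "B.x")
  zero <- trait_matrix(zero_aff, data.frame(
    taxon = "z", genus = "g", family = "f", superfamily = "sf"),
    trait_of = c(A.x = "A", A.y = "A", B.x = "B"))
  sz <- standardize_affinities(zero)
  expect_true(all(is.na(sz$affinity[, c("A.x", "A.y")])))
  expect_true(all(is.na(std$affinity["t4", c("A.x", "A.y")])))
  # categories of each non-missing trait sum to 1
  for (tr in c("A", "B")) {
    cols <- names(std$trait_of)[std$trait_of == tr]
    s <- rowSums(std$affinity[, cols])
    expect_true(all(abs(s[!is.na(s)] - 1) < 1e-12))
  }
})

test_that("imputation walks the family-then-superfamily ladder", {
  tm <- standardize_affinities(make_toy_traits())
  imp <- impute_missing(tm)
  # t4 misses trait A; family mates t1 (0,1), t2 (0.5,0.5) -> (0.25, 0.75)
  expect_equal(unname(imp$affinity["t4", c("A.x", "A.y")]), c(0.25, 0.75))
  # t5 misses trait B; family mate t3 has (0, 0.5, 0.5)
  expect_equal(unname(imp$affinity["t5", c("B.x", "B.y", "B.z")]),
               c(0, 0.5, 0.5))
  expect_false(anyNA(imp$affinity))

  # superfamily fallback: remove the family donor
  aff <- rbind(x = c(NA, NA), y = c(0.2, 0.8), z = c(0.6, 0.4))
  colnames(aff) <- c("A.x", "A.y")
  tax <- data.frame(taxon = c("x", "y", "z"), genus = c("g1", "g2", "g3"),
                    family = c("fx", "fy", "fz"),
                    superfamily = c("sf", "sf", "sf"))
  imp2 <- impute_missing(trait_matrix(aff, tax, standardized = TRUE))
  expect_equal(unname(imp2$affinity["x", ]), c(0.4, 0.6))

  # orphan taxa are dropped with a warning
  tax$superfamily <- c("sf_lonely", "sf", "sf")
  expect_warning(
    imp3 <- impute_missing(trait_matrix(aff, tax, standardized = TRUE)),
    "excluded")
  expect_false("x" %in% rownames(imp3$affinity))
})

test_that("Gower dissimilarity matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    x <- matrix(runif(n * 6), n, dimnames = list(paste0("t", 1:n), NULL))
    colnames(x) <- paste0("v", 1:6)
    x[sample(length(x), 4)] <- NA            # exercise pairwise deletion
    x[, 6] <- 0.5                            # zero-range variable
    D <- gower_dissimilarity(x)
    expect_equal(D, gower_brute(x), tolerance = 1e-12)
    expect_true(all(abs(D - t(D)) < 1e-12, na.rm = TRUE))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1, na.rm = TRUE))
  }
  # identical profiles are at distance 0; opposite extremes at distance 1
  y <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  Dy <- gower_dissimilarity(y)
  expect_equal(Dy["a", "b"], 0)
  expect_equal(Dy["a", "c"], 1)
  # cross-check against the field-standard implementation when complete
  skip_if_not_installed("cluster")
  z <- matrix(runif(40), 8)
  expect_equal(unname(gower_dissimilarity(z)[lower.tri(diag(8))]),
               as.numeric(cluster::daisy(z, metric = "gower")),
               tolerance = 1e-10)
})

test_that("Ward clustering recovers separable structure deterministically", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20, 0, 0.05), 10),
             matrix(rnorm(20, 1, 0.05), 10))
  rownames(x) <- paste0("t", 1:20)
  D <- gower_dissimilarity(x)
  g <- ward_cluster(D, 2)
  expect_length(unique(g$labels[1:10]), 1)
  expect_length(unique(g$labels[11:20]), 1)
  expect_false(g$labels[1] == g$labels[11])
  # k = n gives singletons; duplicated rows share a cluster at any k
  expect_length(unique(ward_cluster(D, 20)$labels), 20)
  xd <- rbind(x, t21 = x[1, ])
  gd <- ward_cluster(gower_dissimilarity(xd), 3)
  expect_equal(unname(gd$labels["t21"]), unname(gd$labels["t1"]))
  expect_error(ward_cluster(D, 0), "k must")
})

test_that("WSS curve is non-increasing, hits 0 at k = n, and knees at the
           true cluster number", {
  set.seed(11)
  # three tight clusters at the corners of a simplex (mutually equidistant,
  # like contrasting trait archetypes)
  centers <- diag(3)
  x <- do.call(rbind, lapply(1:3, function(cc)
    matrix(rnorm(24, 0, 0.03), 8, 3) + rep(centers[cc, ], each = 8)))
  rownames(x) <- paste0("t", 1:24)
  D <- gower_dissimilarity(x)
  w <- wss_curve(D, 23)
  expect_true(all(diff(w$curve$wss) <= 1e-9))
  expect_equal(w$suggested_k, 3)
  w2 <- wss_curve(D, 24)
  expect_equal(w2$curve$wss[24], 0)
})

test_that("ANOSIM agrees with hand-ranked and brute-force oracles", {
  # 4 taxa, 2 groups of 2, both within-dissimilarities below all
  # between-dissimilarities: ranks within {1,2}, between {3,4,5,6},
  # R = (4.5 - 1.5) / 3 = 1
  D <- matrix(0, 4, 4)
  D[1, 2] <- 0.1; D[3, 4] <- 0.2
  D[1, 3] <- 0.5; D[1, 4] <- 0.6; D[2, 3] <- 0.7; D[2, 4] <- 0.8
  D <- D + t(D)
  g <- c("a", "a", "b", "b")
  res <- anosim(D, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_true(res$p > 0 && res$p <= 1)

  # random matrices: statistic equals the brute-force computation and is
  # invariant to relabelling the groups
  set.seed(21)
  for (rep in 1:5) {
    n <- 8
    x <- matrix(runif(n * 4), n, dimnames = list(paste0("t", 1:n), NULL))
    Dx <- gower_dissimilarity(x)
    gx <- rep(c("g1", "g2"), each = 4)
    r1 <- anosim(Dx, gx, n_perm = 19, seed = rep)
    expect_equal(r1$R, anosim_R_brute(Dx, gx), tolerance = 1e-12)
    r2 <- anosim(Dx, ifelse(gx == "g1", "zzz", "aaa"), n_perm = 19, seed = rep)
    expect_equal(r1$R, r2$R)
    expect_true(abs(r1$R) <= 1)
  }
  expect_error(anosim(D, c("a", "a", "a", "b")), "at least two members")

  # cross-check the statistic against the community-ecology standard
  skip_if_not_installed("vegan")
  set.seed(99)
  x <- matrix(runif(60), 12)
  Dx <- as.matrix(dist(x)); dimnames(Dx) <- list(paste0("t", 1:12), paste0("t", 1:12))
  gx <- rep(c("u", "v"), each = 6)
  expect_equal(anosim(Dx, gx, n_perm = 9, seed = 1)$R,
               as.numeric(vegan::anosim(as.dist(Dx), gx,
                                        permutations = 9)$statistic),
               tolerance = 1e-10)
})

test_that("multilevel pattern analysis matches exhaustive enumeration", {
  # perfect indicator of one group with equal sizes: r_pb = 1
  g <- rep(c("A", "B"), each = 4)
  aff <- cbind(ind = c(rep(1, 4), rep(0, 4)),
               flat = rep(0.5, 8),
               noise = c(0.9, 0.1, 0.8, 0.2, 0.15, 0.85, 0.3, 0.7))
  tax <- data.frame(taxon = paste0("t", 1:8), genus = paste0("g", 1:8),
                    family = "f", superfamily = "sf")
  rownames(aff) <- tax$taxon
  colnames(aff) <- c("A.ind", "A.flat", "B.noise")
  tm <- trait_matrix(aff, tax, standardized = TRUE,
                     trait_of = c(A.ind = "A", A.flat = "A", B.noise = "B"))
  gl <- setNames(g, tax$taxon)
  res <- multilevel_pattern(tm, gl, n_perm = 99, seed = 3)
  expect_equal(res$r_pb[res$category == "A.ind"], 1)
  expect_equal(res$combination[res$category == "A.ind"], "A")
  # constant category is degenerate and reported as 0
  expect_true(res$degenerate[res$category == "A.flat"])
  expect_equal(res$r_pb[res$category == "A.flat"], 0)

  # 6-taxon, 3-group instance against the brute-force subset enumeration
  set.seed(12)
  for (rep in 1:4) {
    g3 <- setNames(rep(c("A", "B", "C"), each = 2), paste0("t", 1:6))
    v <- runif(6)
    aff3 <- cbind(T.v = v)
    rownames(aff3) <- names(g3)
    tm3 <- trait_matrix(aff3, data.frame(
      taxon = names(g3), genus = names(g3), family = "f",
      superfamily = "sf"), standardized = TRUE, trait_of = c(T.v = "T"))
    got <- multilevel_pattern(tm3, g3, n_perm = 19, seed = rep)
    want <- indicator_brute(v, unname(g3))
    expect_equal(got$r_pb, want$r, tolerance = 1e-12)
    expect_equal(got$combination, want$combination)
  }
})
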