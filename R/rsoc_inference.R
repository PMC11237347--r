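#' The five RSOC regression models
#'
#' Each ranked species occupancy curve (RSOC) is fitted with one linear and
#' four nonlinear regressions of relative occupancy `O` on rank `R`. Each
#' model corresponds to an occupancy-frequency-distribution (OFD) pattern:
#'
#' * `exp_concave` `O = y0 + a exp(-b R)` — unimodal satellite-dominant;
#' * `power_exp` `O = a R^b exp(-c R)` — bimodal (truncated) if `b > 0`,
#'   unimodal (truncated) if `b <= 0`;
#' * `sig_symmetric` `O = a / (1 + exp(-b R + c))` — bimodal symmetric;
#' * `sig_asymmetric` `O = a (1 - exp(-b R^c))` — bimodal asymmetric;
#' * `linear` `O = a R + b` — uniform/random.
#'
#' Initial parameter values are the conventional ones for this model set.
#' The printed initial values of the power-exponential model do not name the
#' model's own parameters `(a, b, c)`; they are mapped positionally, giving
#' `a = 1, b = 0.01, c = 0.01` (overridable via `start`).
#'
#' @return Named list of model specifications (`formula`, `start`, `n_par`,
#'   `family`).
#' @export
rsoc_models <- function() {
  list(
    exp_concave = list(
      formula = O ~ y0 + a * exp(-b * R),
      start = c(y0 = 0.01, a = 1.0, b = 0.01),
      n_par = 3L, family = "unimodal"),
    power_exp = list(
      formula = O ~ a * R^b * exp(-c * R),
      start = c(a = 1.0, b = 0.01, c = 0.01),
      n_par = 3L, family = "power_exp"),   # family decided by sign of b-hat
    sig_symmetric = list(
      formula = O ~ a / (1 + exp(-b * R + c)),
      start = c(a = 1.0, b = -0.1, c = -1.0),
      n_par = 3L, family = "bimodal"),
    sig_asymmetric = list(
      formula = O ~ a * (1 - exp(-b * R^c)),
      start = c(a = 1.0, b = -1.0, c = -1.0),
      n_par = 3L, family = "bimodal"),
    linear = list(
      formula = O ~ a * R + b,
      start = c(a = -0.01, b = 1.0),
      n_par = 2L, family = "random")
  )
}

#' Ranked species occupancy curve of an SRS
#'
#' Relative occupancy of each taxon is the number of ARSs of the SRS in
#' which it occurs divided by the number of ARSs; taxa absent from every
#' ARS are excluded. Occupancies are sorted in decreasing order and ranked
#' 1..S; ties are broken by taxon identifier so runs are reproducible.
#'
#' @param srs an `srs`.
#' @param community the `community_data` the SRS was drawn from (for taxon
#'   names).
#' @param taxa_subset optional integer or character vector restricting the
#'   curve to one dispersal group's taxa.
#' @return Object of class `rsoc`: data.frame `taxon, rank, occupancy` with
#'   attributes `n_ars` and `S`; zero rows if the subset is empty.
#' @export
occupancies <- function(srs, community, taxa_subset = NULL) {
  counts <- table(unlist(lapply(srs$ars, `[[`, "taxa")))
  ids <- as.integer(names(counts))
  keep <- rep(TRUE, length(ids))
  if (!is.null(taxa_subset)) {
    if (is.character(taxa_subset))
      taxa_subset <- match(taxa_subset, community$taxa)
    keep <- ids %in% taxa_subset
  }
  ids <- ids[keep]
  occ <- as.numeric(counts[keep]) / srs$n_ars
  taxon <- community$taxa[ids]
  ord <- order(-occ, taxon)
  out <- data.frame(taxon = taxon[ord], rank = seq_along(ord),
                    occupancy = occ[ord], stringsAsFactors = FALSE)
  structure(out, class = c("rsoc", "data.frame"),
            n_ars = srs$n_ars, S = nrow(out))
}

#' Fit one RSOC model by damped least squares
#'
#' Nonlinear models are fitted with the Levenberg-Marquardt algorithm
#' (iteration cap 999, gradient/step tolerance 1e-8) from the model's
#' initial parameters; the linear model is fitted by ordinary least
#' squares. Non-convergence or a non-finite residual sum of squares sets
#' `converged = FALSE` (such fits are later excluded from the Akaike-weight
#' set).
#'
#' @param rsoc an `rsoc`, or any data.frame with `rank` and `occupancy`.
#' @param model name of a model in [rsoc_models()], or a model spec list.
#' @param start optional named vector overriding the initial parameters.
#' @return Object of class `rsoc_fit`: list `model`, `params`, `rss`, `n`,
#'   `k` (parameters + 1 for the residual variance), `aicc`, `converged`.
#' @export
fit_model <- function(rsoc, model, start = NULL) {
  spec <- if (is.character(model)) rsoc_models()[[model]] else model
  name <- if (is.character(model)) model else model$name
  if (is.null(spec)) stop("unknown RSOC model: ", model)
  R <- rsoc$rank
  O <- rsoc$occupancy
  n <- length(R)
  k <- spec$n_par + 1L
  fail <- function() structure(
    list(model = name, params = NULL, rss = NA_real_, n = n, k = k,
         aicc = NA_real_, converged = FALSE), class = "rsoc_fit")
  if (n - k - 1L < 1L) return(fail())   # AICc denominator must be >= 1

  if (identical(name, "linear")) {
    lf <- stats::lm(O ~ R)
    params <- c(a = unname(stats::coef(lf)[2L]),
                b = unname(stats::coef(lf)[1L]))
    rss <- sum(stats::residuals(lf)^2)
  } else {
    st <- if (is.null(start)) spec$start else start
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        spec$formula, data = data.frame(R = R, O = O),
        start = as.list(st),
        control = minpack.lm::nls.lm.control(
          maxiter = 999, ftol = 1e-8, ptol = 1e-8, gtol = 1e-8))),
      error = function(e) NULL)
    if (is.null(fit)) return(fail())
    params <- stats::coef(fit)
    rss <- sum(stats::residuals(fit)^2)
  }
  if (!is.finite(rss) || any(!is.finite(params))) return(fail())
  structure(list(model = name, params = params, rss = rss, n = n, k = k,
                 aicc = aicc(rss, n, k), converged = TRUE),
            class = "rsoc_fit")
}

#' Small-sample Akaike information criterion for least squares
#'
#' `AICc = n log(rss / n) + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts the
#' regression parameters plus one for the residual variance. A floor of
#' `1e-12 * n` on the residual sum of squares prevents an infinite score on
#' degenerate exact fits; such a fit still dominates the weight set, which
#' is the intended behaviour.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param k number of parameters including the residual variance.
#' @return AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc needs n > k + 1")
  rss <- max(rss, 1e-12 * n)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit all candidate RSOC models to one curve
#'
#' @param rsoc an `rsoc`.
#' @param models model set from [rsoc_models()].
#' @return List of `rsoc_fit`, one per model.
#' @export
fit_rsoc_models <- function(rsoc, models = rsoc_models()) {
  fits <- lapply(names(models), function(m) fit_model(rsoc, m))
  names(fits) <- names(models)
  fits
}

#' Akaike weights over a candidate set
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min AICc`, computed over the converged fits only;
#' non-converged fits get weight 0. Weights are invariant to adding a
#' constant to every AICc.
#'
#' @param fits list of `rsoc_fit`.
#' @return The same list with a `weight` element added to each fit.
#' @export
akaike_weights <- function(fits) {
  ok <- vapply(fits, `[[`, TRUE, "converged")
  if (!any(ok)) stop("no converged fits to weight")
  aic <- vapply(fits[ok], `[[`, 0, "aicc")
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  wi <- stats::setNames(rep(0, length(fits)), names(fits))
  wi[names(w)] <- w
  for (m in names(fits)) fits[[m]]$weight <- unname(wi[m])
  fits
}

#' Classify pattern probabilities from weighted fits
#'
#' Sums Akaike weights over the model families of each OFD pattern:
#' bimodal = sigmoidal symmetric + sigmoidal asymmetric + power exponential
#' with fitted `b > 0`; unimodal = exponential concave + power exponential
#' with fitted `b <= 0`; random = linear.
#'
#' @param fits weighted fits from [akaike_weights()].
#' @return Object of class `pattern_probs`: list `w_bimodal`, `w_unimodal`,
#'   `w_random`, `b_hat_powexp`, `S`, `converged` (named logical).
#' @export
classify_patterns <- function(fits) {
  w <- vapply(fits, function(f) f$weight %||% 0, 0)
  b_hat <- if (isTRUE(fits$power_exp$converged))
    unname(fits$power_exp$params["b"]) else NA_real_
  pw_bi <- if (!is.na(b_hat) && b_hat > 0) w[["power_exp"]] else 0
  pw_uni <- if (!is.na(b_hat) && b_hat <= 0) w[["power_exp"]] else 0
  structure(list(
    w_bimodal = w[["sig_symmetric"]] + w[["sig_asymmetric"]] + pw_bi,
    w_unimodal = w[["exp_concave"]] + pw_uni,
    w_random = w[["linear"]],
    b_hat_powexp = b_hat,
    S = fits[[1L]]$n,
    converged = vapply(fits, `[[`, TRUE, "converged")
  ), class = "pattern_probs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one SRS: RSOC, model fits, pattern probabilities
#'
#' Builds the ranked species occupancy curve for each dispersal group (and,
#' if `groups` is `NULL`, the pooled assemblage), fits the five candidate
#' models, converts AICc into Akaike weights, and sums them into pattern
#' probabilities. Groups whose curve is too short to fit every model's
#' AICc (fewer taxa than `min_S`) are skipped.
#'
#' @param srs an `srs`.
#' @param community the source `community_data`.
#' @param groups named character vector taxon -> group (or a
#'   `dispersal_groups`), or `NULL` for the pooled assemblage.
#' @param min_S minimum taxa per curve (default 6: the largest model has
#'   3 parameters, and AICc needs `n - k - 1 >= 1`).
#' @return data.frame with one row per analysed group: `group, S,
#'   w_bimodal, w_unimodal, w_random, b_hat_powexp, converged_mask`, plus
#'   attribute `skipped` (character vector of skipped groups).
#' @export
analyze_srs <- function(srs, community, groups = NULL, min_S = 6L) {
  if (inherits(groups, "dispersal_groups")) groups <- groups$labels
  subsets <- if (is.null(groups)) list(all = NULL) else
    split(names(groups), groups)
  skipped <- character(0)
  rows <- lapply(names(subsets), function(gname) {
    r <- occupancies(srs, community, taxa_subset = subsets[[gname]])
    if (nrow(r) < min_S) {
      skipped <<- c(skipped, gname)
      return(NULL)
    }
    fits <- tryCatch(akaike_weights(fit_rsoc_models(r)),
                     error = function(e) NULL)
    if (is.null(fits)) {        # zero converged fits: skip this cell
      skipped <<- c(skipped, gname)
      return(NULL)
    }
    p <- classify_patterns(fits)
    data.frame(group = gname, S = nrow(r),
               w_bimodal = p$w_bimodal, w_unimodal = p$w_unimodal,
               w_random = p$w_random, b_hat_powexp = p$b_hat_powexp,
               converged_mask = paste(as.integer(p$converged), collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "skipped") <- skipped
  out
}

#' Analyse a whole ensemble of SRSs
#'
#' @param ensemble list of `srs` from [generate_ensemble()].
#' @param community the source `community_data`.
#' @param groups taxon -> group labels, or `NULL` for pooled curves.
#' @param min_S minimum taxa per curve.
#' @return data.frame of per-SRS records: `srs_index, extent, group, S,
#'   w_bimodal, w_unimodal, w_random, b_hat_powexp, converged_mask`.
#' @export
analyze_ensemble <- function(ensemble, community, groups = NULL,
                             min_S = 6L) {
  rows <- lapply(ensemble, function(s) {
    rec <- analyze_srs(s, community, groups = groups, min_S = min_S)
    if (!nrow(rec)) return(NULL)
    cbind(data.frame(srs_index = s$index, extent = s$extent,
                     stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, rows)
}
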