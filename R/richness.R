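# Island species-richness modelling: migrant-based island inclusion,
# Gaussian linear models of log10 richness, bidirectional AIC stepwise
# selection, lmg hierarchical variance partitioning, and the
# residual-difference estimator of glacial-maximum (LGM) colonizers.

#' Filter islands by recorded migrant species
#'
#' An island enters the analysis when at least `min_present` of the
#' listed highly-mobile migrant species are recorded there — a minimal
#' surveying standard.
#'
#' @param m an [incidence_matrix()] over all candidate islands.
#' @param migrant_species character vector of migrant species labels
#'   (classically 5).
#' @param min_present minimum migrants required (default 4).
#' @return Character vector of retained island labels.
#' @export
filter_islands_by_migrants <- function(m, migrant_species, min_present = 4L) {
  missing <- setdiff(migrant_species, colnames(m))
  .assert(length(missing) == 0,
          paste("migrant species absent from matrix:",
                paste(missing, collapse = ", ")))
  hits <- rowSums(unclass(m)[, migrant_species, drop = FALSE])
  rownames(m)[hits >= min_present]
}

# Transformed design frame: log10 on richness, IA, IS, SR (IS gets a +1
# offset when any island has IS = 0).
.richness_frame <- function(cov) {
  is_off <- if (any(cov$IS == 0)) {
    message("richness model: IS = 0 present, using log10(IS + 1)")
    1
  } else 0
  data.frame(
    log_richness = log10(cov$richness),
    MT = cov$MT, AP = cov$AP,
    log_IA = log10(cov$IA), EL = cov$EL,
    log_IS = log10(cov$IS + is_off),
    log_SR = log10(cov$SR), PC = cov$PC,
    row.names = cov$island
  )
}

.all_predictors <- c("MT", "AP", "log_IA", "EL", "log_IS", "log_SR", "PC")

# Map user-facing predictor names (IA, IS, SR) to design columns.
.design_names <- function(predictors) {
  map <- c(MT = "MT", AP = "AP", IA = "log_IA", EL = "EL", IS = "log_IS",
           SR = "log_SR", PC = "PC")
  unknown <- setdiff(predictors, c(names(map), unname(map)))
  .assert(length(unknown) == 0,
          paste("unknown predictors:", paste(unknown, collapse = ", ")))
  unname(ifelse(predictors %in% names(map), map[predictors], predictors))
}

#' Fit a richness model
#'
#' Gaussian identity-link model of `log10(richness)` on the offered
#' predictors; area, isolation and source richness enter
#' log10-transformed (`IS = 0` handled by a +1 offset).
#'
#' @param cov a [covariate_table()].
#' @param predictors subset of `MT, AP, IA, EL, IS, SR, PC` (default
#'   all).
#' @return List of class `richness_fit`: `fit` (`lm`), `coefficients`
#'   (Est, SE, t, p), `residuals_log` (log10 scale),
#'   `residuals_count` (species scale, `obs - 10^fitted`),
#'   `r_squared`, `aic`, `predictors`.
#' @export
fit_richness <- function(cov, predictors = c("MT", "AP", "IA", "EL", "IS",
                                             "SR", "PC")) {
  stopifnot(inherits(cov, "covariate_table"))
  .assert(all(cov$richness > 0), "richness must be positive for log transform")
  preds <- .design_names(predictors)
  df <- .richness_frame(cov)
  .assert(nrow(df) >= length(preds) + 2,
          "too few islands for the requested predictors")
  fml <- if (length(preds)) {
    as.formula(paste("log_richness ~", paste(preds, collapse = " + ")))
  } else {
    log_richness ~ 1
  }
  # embed the data in the call so step()/update() can re-evaluate it
  fit <- do.call(lm, list(formula = fml, data = df))
  if (any(is.na(coef(fit)))) {
    stop("singular design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  structure(list(fit = fit,
                 coefficients = summary(fit)$coefficients,
                 residuals_log = resid(fit),
                 residuals_count = cov$richness - 10^fitted(fit),
                 r_squared = summary(fit)$r.squared,
                 aic = .gaussian_aic(fit),
                 predictors = preds,
                 data = df),
            class = "richness_fit")
}

# Gaussian profile AIC: n * ln(RSS / n) + 2k, k = number of estimated
# mean parameters (matches stats::extractAIC for lm).
.gaussian_aic <- function(fit) {
  n <- length(resid(fit))
  rss <- sum(resid(fit)^2)
  n * log(rss / n) + 2 * length(coef(fit))
}

#' Bidirectional AIC stepwise selection of a richness model
#'
#' Starts from the full model over the candidate predictors and applies
#' bidirectional stepwise search minimizing the Gaussian profile AIC
#' `n ln(RSS/n) + 2k` (via [stats::step()]); deterministic given the
#' input.
#'
#' @param cov a [covariate_table()].
#' @param candidates candidate predictor names (default all seven).
#' @return A `richness_fit` for the selected model.
#' @export
stepwise_aic <- function(cov, candidates = c("MT", "AP", "IA", "EL", "IS",
                                             "SR", "PC")) {
  .assert(length(candidates) >= 2, "need >= 2 candidate predictors")
  full <- fit_richness(cov, candidates)
  sel <- step(full$fit, direction = "both", trace = 0,
              scope = list(lower = ~1))
  kept_design <- attr(terms(sel), "term.labels")
  back <- c(MT = "MT", AP = "AP", log_IA = "IA", EL = "EL", log_IS = "IS",
            log_SR = "SR", PC = "PC")
  fit_richness(cov, unname(back[kept_design]))
}

#' lmg relative importance of predictors
#'
#' Decomposes the model R^2 into per-predictor shares: a predictor's
#' share is its average incremental R^2 over all orderings in which the
#' predictors can enter the model (computed over subsets with
#' combinatorial weights). Shares always sum to the full-model R^2.
#'
#' @param fit an `lm` or `richness_fit` with at most 8 predictors.
#' @return Named numeric vector of R^2 shares (same scale as R^2; for
#'   a percentage multiply by 100).
#' @export
lmg_importance <- function(fit) {
  if (inherits(fit, "richness_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  preds <- attr(terms(fit), "term.labels")
  p <- length(preds)
  .assert(p >= 1, "lmg_importance: no predictors")
  .assert(p <= 8, "lmg_importance: > 8 predictors; ordering enumeration too large")
  mf <- stats::model.frame(fit)
  yname <- names(mf)[1]
  r2 <- function(sub) {
    f <- if (length(sub)) {
      as.formula(paste(yname, "~", paste(sub, collapse = " + ")))
    } else {
      as.formula(paste(yname, "~ 1"))
    }
    summary(lm(f, data = mf))$r.squared
  }
  # R^2 of every predictor subset, keyed by sorted member string
  subsets <- unlist(lapply(0:p, function(k) {
    combn(preds, k, simplify = FALSE)
  }), recursive = FALSE)
  key <- function(s) paste0("S:", paste(sort(s), collapse = "|"))
  r2s <- setNames(vapply(subsets, r2, numeric(1)),
                  vapply(subsets, key, character(1)))
  shares <- setNames(numeric(p), preds)
  for (x in preds) {
    others <- setdiff(preds, x)
    total <- 0
    for (k in 0:length(others)) {
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (s in combn(others, k, simplify = FALSE)) {
        total <- total + w * (r2s[[key(c(s, x))]] - r2s[[key(s)]])
      }
    }
    shares[x] <- total
  }
  shares
}

#' Residual-difference estimate of LGM colonizers
#'
#' For each island that had a Pleistocene land connection, the
#' difference between its richness residual under the
#' contemporary-only model (`Res.1`, without PC) and under the full
#' model including PC (`Res.2`) estimates the number of species that
#' colonized over the land bridge and persisted. Residuals are on the
#' species-count scale (`observed - 10^fitted`).
#'
#' @param fit_noPC,fit_withPC `richness_fit`s on the identical island
#'   set, without and with the PC predictor.
#' @param lgm_islands island labels to report.
#' @return Data frame: `island`, `res1`, `res2`, `diff = res1 - res2`.
#' @export
lgm_estimate <- function(fit_noPC, fit_withPC, lgm_islands) {
  r1 <- fit_noPC$residuals_count
  r2 <- fit_withPC$residuals_count
  names(r1) <- rownames(fit_noPC$data)
  names(r2) <- rownames(fit_withPC$data)
  .assert(identical(names(r1), names(r2)),
          "lgm_estimate: fits must cover the identical island set")
  missing <- setdiff(lgm_islands, names(r1))
  .assert(length(missing) == 0,
          paste("islands absent from fits:", paste(missing, collapse = ", ")))
  data.frame(island = lgm_islands,
             res1 = unname(r1[lgm_islands]),
             res2 = unname(r2[lgm_islands]),
             diff = unname(r1[lgm_islands] - r2[lgm_islands]),
             stringsAsFactors = FALSE)
}

#' LGM residual differences from precomputed residual columns
#'
#' Same arithmetic as [lgm_estimate()] when only the two residual
#' columns of a published table are available as inputs.
#'
#' @param res1,res2 residuals (species scale) without and with the PC
#'   predictor.
#' @return `res1 - res2`.
#' @export
lgm_diff <- function(res1, res2) {
  .assert(length(res1) == length(res2), "lgm_diff: unequal lengths")
  res1 - res2
}
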