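# Community structure: NODF nestedness with three null models
# (equiprobable EE, proportional CE, fixed-marginal FF via the curveball
# trade algorithm), occupancy-based widespread/rare partitioning, and
# Sorensen beta-diversity decomposition into turnover and nestedness.

#' Pack an incidence matrix
#'
#' Sorts rows and columns by decreasing marginal totals; ties broken by
#' current label order (stable sort). Idempotent.
#'
#' @param m an [incidence_matrix()].
#' @return The packed [incidence_matrix()].
#' @export
pack_matrix <- function(m) {
  .assert(nrow(m) > 0 && ncol(m) > 0, "pack_matrix: empty matrix")
  ro <- order(-rowSums(m), rownames(m))
  co <- order(-colSums(m), colnames(m))
  incidence_matrix(unclass(m)[ro, co, drop = FALSE])
}

#' NODF nestedness metric
#'
#' Nestedness based on Overlap and Decreasing Fill, on a 0-100 scale.
#' For every unordered pair of rows the paired overlap is
#' `100 * shared / fill_smaller` when the fills differ strictly (the
#' row with smaller fill must be a partial subset of the fuller one),
#' and 0 for equal fills; likewise over column pairs. NODF is the mean
#' over all row pairs and column pairs. Packing is internal, so the
#' value is invariant to input row/column permutations.
#'
#' @param m an [incidence_matrix()] with at least 2 rows and 2 columns.
#' @return NODF in `[0, 100]`.
#' @export
nodf <- function(m) {
  .assert(nrow(m) >= 2 && ncol(m) >= 2, "nodf: need >= 2 rows and >= 2 columns")
  m <- unclass(m)
  storage.mode(m) <- "numeric"
  pair_sum <- function(x) {
    f <- rowSums(x)
    s <- tcrossprod(x)              # shared presences per row pair
    fi <- matrix(f, nrow(x), nrow(x))
    fj <- t(fi)
    # for each unordered pair, overlap relative to the strictly smaller fill
    contrib <- ifelse(fi > fj & fj > 0, 100 * s / fj, 0) +
      ifelse(fj > fi & fi > 0, 100 * s / fi, 0)
    sum(contrib[upper.tri(contrib)])
  }
  n_pairs <- choose(nrow(m), 2) + choose(ncol(m), 2)
  (pair_sum(m) + pair_sum(t(m))) / n_pairs
}

#' Draw one null incidence matrix
#'
#' Three classical randomizations of a presence-absence matrix:
#' \describe{
#'   \item{EE}{equiprobable rows and columns — the observed number of
#'     presences is placed uniformly at random among all cells.}
#'   \item{CE}{proportional rows and columns — each cell is an
#'     independent Bernoulli draw with probability
#'     `(r_i/C + c_j/R)/2`, the mean of the observed row and column
#'     fill proportions.}
#'   \item{FF}{fixed rows and columns — exact marginal preservation via
#'     the curveball trade algorithm; `trades` trades are applied from
#'     the supplied state.}
#' }
#'
#' @param m observed [incidence_matrix()].
#' @param model `"EE"`, `"CE"` or `"FF"`.
#' @param trades number of curveball trades for FF (default
#'   `5 * sum(m)`).
#' @return A null [incidence_matrix()] of the same dimension.
#' @export
null_matrix <- function(m, model = c("EE", "CE", "FF"), trades = NULL) {
  model <- match.arg(model)
  R <- nrow(m); C <- ncol(m)
  fill <- sum(m)
  out <- switch(model,
    EE = {
      cells <- matrix(0L, R, C)
      cells[sample.int(R * C, fill)] <- 1L
      cells
    },
    CE = {
      p <- outer(rowSums(m) / C, colSums(m) / R, `+`) / 2
      if (any(p > 1)) {
        warning("null_matrix: CE cell probability > 1 clipped")
        p <- pmin(p, 1)
      }
      matrix(rbinom(R * C, 1L, p), R, C)
    },
    FF = {
      if (is.null(trades)) trades <- 5L * fill
      curveball(m, trades)
    })
  incidence_matrix(out, islands = rownames(m), species = colnames(m))
}

#' Curveball trades on a binary matrix
#'
#' Applies `trades` random pair-of-rows trades, each exchanging a random
#' subset of the rows' non-shared presences, preserving both row and
#' column sums exactly. The stationary distribution of the resulting
#' chain is uniform over all matrices with the observed marginals.
#'
#' @param m binary matrix.
#' @param trades number of trades.
#' @return A binary matrix with identical row and column sums.
#' @export
curveball <- function(m, trades) {
  m <- unclass(m)
  R <- nrow(m)
  rows <- lapply(seq_len(R), function(i) which(m[i, ] == 1L))
  for (t in seq_len(trades)) {
    ab <- sample.int(R, 2L)
    sa <- rows[[ab[1]]]; sb <- rows[[ab[2]]]
    common <- intersect(sa, sb)
    ua <- setdiff(sa, common); ub <- setdiff(sb, common)
    if (length(ua) == 0 || length(ub) == 0) next
    pool <- c(ua, ub)
    pick <- sample(pool, length(ua))
    rows[[ab[1]]] <- c(common, pick)
    rows[[ab[2]]] <- c(common, setdiff(pool, pick))
  }
  out <- matrix(0L, R, ncol(m))
  for (i in seq_len(R)) out[i, rows[[i]]] <- 1L
  dimnames(out) <- dimnames(m)
  out
}

#' NODF significance test against a null model
#'
#' Compares the observed NODF with `n_null` matrices from one null
#' model. For FF the curveball chain starts with `10 * fill` burn-in
#' trades and applies `5 * fill` trades between retained samples.
#' The z-score is `(obs - null mean) / null sd`; the empirical p-value
#' is two-sided, add-one:
#' `p = (1 + #{|null - mean| >= |obs - mean|}) / (n_null + 1)`.
#'
#' @param m an [incidence_matrix()].
#' @param model `"EE"`, `"CE"` or `"FF"`.
#' @param n_null number of null matrices (default 999).
#' @param seed optional RNG seed.
#' @return A list of class `nodf_result`: `observed`, `model`,
#'   `null_mean`, `null_sd`, `z` (`NA` when the null sd is 0), `p`,
#'   `n_null`, `stars` (`|z|` > 1.96/2.58/3.29 thresholds).
#' @export
nodf_test <- function(m, model = c("EE", "CE", "FF"), n_null = 999L,
                      seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  obs <- nodf(m)
  nulls <- numeric(n_null)
  if (model == "FF") {
    fill <- sum(m)
    state <- curveball(m, 10L * fill)            # burn-in
    for (k in seq_len(n_null)) {
      state <- curveball(state, 5L * fill)
      nulls[k] <- nodf(incidence_matrix(state))
    }
  } else {
    for (k in seq_len(n_null)) nulls[k] <- nodf(null_matrix(m, model))
  }
  mu <- mean(nulls)
  s <- sd(nulls)
  z <- if (s > 0) (obs - mu) / s else NA_real_
  p <- (1 + sum(abs(nulls - mu) >= abs(obs - mu))) / (n_null + 1)
  stars <- if (is.na(z)) "" else
    c("", "*", "**", "***")[findInterval(abs(z), c(1.96, 2.58, 3.29)) + 1]
  structure(list(observed = obs, model = model, null_mean = mu, null_sd = s,
                 z = z, p = p, n_null = n_null, stars = stars),
            class = "nodf_result")
}

#' @export
print.nodf_result <- function(x, ...) {
  cat(sprintf("NODF = %.3f vs %s null (n = %d): mean = %.3f, z = %.3f%s, p = %.4f\n",
              x$observed, x$model, x$n_null, x$null_mean,
              ifelse(is.na(x$z), NA, x$z), x$stars, x$p))
  invisible(x)
}

#' Split species into widespread and rare subsets
#'
#' Widespread species occur on at least `min_islands` islands (default:
#' more than half, i.e. `ceiling((n_islands + 1) / 2)`, which is 6 of
#' 11); the rest are rare. Both submatrices keep all islands.
#'
#' @param m an [incidence_matrix()].
#' @param min_islands occupancy threshold for "widespread".
#' @return List with `widespread` and `rare` incidence matrices (either
#'   may have zero columns) and the `min_islands` used.
#' @export
split_widespread_rare <- function(m,
                                  min_islands = ceiling((nrow(m) + 1) / 2)) {
  occ <- colSums(m)
  wide <- occ >= min_islands
  if (all(wide) || !any(wide)) {
    message("split_widespread_rare: one side of the partition is empty")
  }
  list(widespread = incidence_matrix(unclass(m)[, wide, drop = FALSE]),
       rare = incidence_matrix(unclass(m)[, !wide, drop = FALSE]),
       min_islands = min_islands)
}

#' Pairwise beta-diversity partition
#'
#' For each island pair with `a` shared and `b`, `c` unique species:
#' Sorensen dissimilarity `bsor = (b + c) / (2a + b + c)`, its turnover
#' (Simpson) component `bsim = min(b, c) / (a + min(b, c))` and the
#' nestedness-resultant component `bnes = bsor - bsim`. The summary
#' ratio is the mean over pairs of `bnes / bsor`; pairs with
#' `bsor = 0` (identical faunas) and pairs involving an empty island
#' are excluded from the mean. The alternative convention (ratio of
#' mean bnes to mean bsor) is reported alongside.
#'
#' @param m an [incidence_matrix()] with >= 2 islands.
#' @return List of class `beta_partition`: matrices `bsor`, `bsim`,
#'   `bnes`; `ratio_mean_of_ratios`; `ratio_of_means`; `n_pairs_used`.
#' @export
beta_partition <- function(m) {
  .assert(nrow(m) >= 2, "beta_partition: need >= 2 islands")
  n <- nrow(m)
  lab <- rownames(m)
  bsor <- bsim <- bnes <- matrix(NA_real_, n, n, dimnames = list(lab, lab))
  ratios <- c(); sors <- c(); ness <- c()
  mm <- unclass(m)
  empty <- rowSums(mm) == 0
  if (any(empty)) {
    message("beta_partition: empty islands excluded from the ratio: ",
            paste(lab[empty], collapse = ", "))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- sum(mm[i, ] & mm[j, ])
      b <- sum(mm[i, ] & !mm[j, ])
      cc <- sum(!mm[i, ] & mm[j, ])
      if (a + b + cc == 0) next
      sor <- (b + cc) / (2 * a + b + cc)
      sim <- if (a + min(b, cc) > 0) min(b, cc) / (a + min(b, cc)) else 0
      bsor[i, j] <- bsor[j, i] <- sor
      bsim[i, j] <- bsim[j, i] <- sim
      bnes[i, j] <- bnes[j, i] <- sor - sim
      if (!empty[i] && !empty[j] && sor > 0) {
        ratios <- c(ratios, (sor - sim) / sor)
        sors <- c(sors, sor)
        ness <- c(ness, sor - sim)
      }
    }
  }
  structure(list(bsor = bsor, bsim = bsim, bnes = bnes,
                 ratio_mean_of_ratios = if (length(ratios)) mean(ratios) else NA_real_,
                 ratio_of_means = if (length(sors)) mean(ness) / mean(sors) else NA_real_,
                 n_pairs_used = length(ratios)),
            class = "beta_partition")
}

#' Regression of island occupancy on dispersal and source frequency
#'
#' Ordinary least-squares regression of each species' frequency on the
#' islands against its dispersal tendency (standardized to `[0, 1]`)
#' and its frequency at source, with lmg variance shares per predictor.
#'
#' @param freq_on_islands numeric vector, islands occupied per species.
#' @param dispersal dispersal tendency per species.
#' @param freq_at_source frequency at source per species.
#' @return List: `fit` (an `lm`), `coefficients` table, `lmg` shares
#'   (fractions of R^2 per predictor), `r_squared`.
#' @export
occupancy_regression <- function(freq_on_islands, dispersal, freq_at_source) {
  .assert(length(freq_on_islands) >= 3, "need >= 3 species")
  df <- data.frame(freq = freq_on_islands, dispersal = dispersal,
                   source = freq_at_source)
  for (v in c("dispersal", "source")) {
    if (sd(df[[v]]) == 0) warning(sprintf("constant predictor '%s': share = 0", v))
  }
  fit <- lm(freq ~ dispersal + source, data = df)
  lmg <- lmg_importance(fit)
  list(fit = fit, coefficients = summary(fit)$coefficients,
       lmg = lmg, r_squared = summary(fit)$r.squared)
}
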