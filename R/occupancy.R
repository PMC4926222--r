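# Occupancy versus genetic differentiation: Spearman correlations and
# the four-quadrant randomization test relating the number of islands a
# species occupies to its among-population differentiation (sqrt Dst).

#' Island occupancy per species
#'
#' @param m an [incidence_matrix()].
#' @return Named integer vector: number of islands occupied per species.
#' @export
occupancy <- function(m) {
  .assert(nrow(m) > 0 && ncol(m) > 0, "occupancy: empty matrix")
  colSums(unclass(m))
}

# All permutations of 1..n (n <= 9), as a matrix with one permutation
# per row. Used for the exact Spearman null.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; for `n <= 9` an exact two-sided permutation
#' p-value is computed by full enumeration instead.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List: `rho`, `p`, `n`, `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman <- function(x, y) {
  n <- length(x)
  .assert(n == length(y), "spearman: unequal lengths")
  .assert(n >= 4, "spearman: need n >= 4")
  .assert(sd(x) > 0 && sd(y) > 0, "spearman: constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    rhos <- as.vector(cor(rx, t(matrix(ry[perms], nrow(perms), n))))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Four-quadrant occupancy-differentiation randomization test
#'
#' Dst values are square-root transformed; species are classed as
#' widespread/rare at half the maximum occupancy and as high/low
#' differentiation at half the maximum `sqrt(Dst)` (species exactly on
#' a boundary go to the lower category). Null replicates independently
#' permute the occupancy vector and the `sqrt(Dst)` vector across
#' species, breaking their association while preserving both marginal
#' distributions. For each quadrant,
#' `q = (#\{null < observed\} + 0.5 * #\{null = observed\}) / n_null`;
#' `q < 0.05` flags a significantly empty quadrant, `q > 0.95` a
#' significantly full one.
#'
#' @param occ per-species island occupancy (counts).
#' @param dst per-species Dst (same species order).
#' @param n_null number of null replicates (default 999).
#' @param seed optional RNG seed.
#' @param null `"permute"` (default; independent permutations of the two
#'   observed vectors, preserving both marginal distributions) or
#'   `"resample"` (uniform draws within the observed ranges: integer
#'   uniform for occupancy, continuous uniform for `sqrt(Dst)`).
#' @param occ_split,d_split optional fixed category boundaries (defaults
#'   half of the observed maxima; supply the global splits when testing
#'   an island's subset).
#' @return List of class `quadrant_result`: `thresholds`, `observed`
#'   (counts WL, WH, RL, RH: widespread/rare x low/high), `q`,
#'   `verdict` (`"empty"`, `"full"`, `"ns"`), `n_null`.
#' @export
quadrant_test <- function(occ, dst, n_null = 999L, seed = NULL,
                          occ_split = NULL, d_split = NULL,
                          null = c("permute", "resample")) {
  null <- match.arg(null)
  n <- length(occ)
  .assert(n == length(dst), "quadrant_test: unequal species vectors")
  .assert(n >= 4, "quadrant_test: need >= 4 species")
  .assert(all(dst >= 0), "quadrant_test: Dst must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- sqrt(dst)
  if (is.null(occ_split)) occ_split <- max(occ) / 2
  if (is.null(d_split)) d_split <- max(d) / 2
  counts <- function(o, dd) {
    wide <- o > occ_split          # boundary goes to the lower (rare) side
    high <- dd > d_split           # boundary goes to the low side
    c(WL = sum(wide & !high), WH = sum(wide & high),
      RL = sum(!wide & !high), RH = sum(!wide & high))
  }
  obs <- counts(occ, d)
  null_counts <- matrix(0L, n_null, 4L,
                        dimnames = list(NULL, names(obs)))
  for (k in seq_len(n_null)) {
    null_counts[k, ] <- if (null == "permute") {
      counts(sample(occ), sample(d))
    } else {
      counts(sample(seq(min(occ), max(occ)), n, replace = TRUE),
             runif(n, min(d), max(d)))
    }
  }
  q <- vapply(names(obs), function(nm) {
    (sum(null_counts[, nm] < obs[nm]) +
       0.5 * sum(null_counts[, nm] == obs[nm])) / n_null
  }, numeric(1))
  verdict <- ifelse(q < 0.05, "empty", ifelse(q > 0.95, "full", "ns"))
  structure(list(thresholds = c(occ_split = occ_split, d_split = d_split),
                 observed = obs, q = q, verdict = verdict, n_null = n_null,
                 null_counts = null_counts),
            class = "quadrant_result")
}

#' Per-island occupancy-differentiation analysis
#'
#' For each island, restricts the species set to those present there and
#' runs [spearman()] (global occupancy vs Dst) plus [quadrant_test()]
#' with the global category boundaries. Islands hosting fewer than 4
#' species are skipped with a message. Each island's null replicates use
#' an RNG substream derived from `seed` and the island's species subset,
#' so islands with identical faunas give identical results.
#'
#' @param m an [incidence_matrix()]; columns must match `names(dst)`.
#' @param dst named per-species Dst vector.
#' @param n_null null replicates per island (default 999).
#' @param seed optional RNG seed.
#' @return Named list per analysed island: `spearman`, `quadrants`,
#'   `n_species`.
#' @export
per_island_analysis <- function(m, dst, n_null = 999L, seed = NULL) {
  .assert(all(colnames(m) %in% names(dst)),
          "per_island_analysis: Dst missing for some species")
  dst <- dst[colnames(m)]
  occ <- occupancy(m)
  d_all <- sqrt(dst)
  occ_split <- max(occ) / 2
  d_split <- max(d_all) / 2
  if (is.null(seed)) seed <- 0L
  out <- list()
  for (isl in rownames(m)) {
    present <- unclass(m)[isl, ] == 1L
    if (sum(present) < 4) {
      message(sprintf("per_island_analysis: %s skipped (<4 species)", isl))
      next
    }
    o <- occ[present]; dd <- dst[present]
    sp <- if (sd(o) > 0 && sd(dd) > 0) spearman(o, dd) else NULL
    # substream keyed on the species subset: identical faunas share it
    isl_seed <- .substream_seed(seed, sum(which(present)) + 7L * sum(present))
    qt <- quadrant_test(o, dd, n_null = n_null, seed = isl_seed,
                        occ_split = occ_split, d_split = d_split)
    out[[isl]] <- list(spearman = sp, quadrants = qt,
                       n_species = sum(present))
  }
  out
}
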