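# Ordination of the area x area mean Gst matrix: classical PCoA,
# Procrustes superimposition onto geography, and an RGB projection of
# the configuration so that colour resemblance tracks genetic
# resemblance among areas.

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: the doubly-centred `-D^2/2` matrix is
#' eigendecomposed and axes with positive eigenvalues are retained;
#' coordinates are eigenvectors scaled by the square roots of their
#' eigenvalues. Missing off-diagonal cells are imputed with the grand
#' mean of the available dissimilarities (count reported); no
#' Cailliez/Lingoes correction is applied — negative-eigenvalue axes
#' are simply dropped.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal). `NA` cells
#'   allowed off-diagonal.
#' @return List of class `pcoa_result`: `coordinates` (rows = objects,
#'   axes ordered by decreasing eigenvalue), `eigenvalues` (positive
#'   only), `n_imputed`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  .assert(isSymmetric(unname(d), tol = 1e-8) ||
            all(abs(d - t(d)) < 1e-8, na.rm = TRUE),
          "pcoa: dissimilarity matrix must be symmetric")
  diag(d) <- 0
  off <- d[upper.tri(d)]
  n_imputed <- sum(is.na(off))
  if (n_imputed > 0) {
    message(sprintf("pcoa: %d missing cells imputed with the grand mean", n_imputed))
    gm <- mean(off, na.rm = TRUE)
    d[is.na(d)] <- gm
  }
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive-axis filter below makes that expected, not exceptional
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = nrow(d) - 1L, eig = TRUE))
  eig <- sc$eig
  keep <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  .assert(length(keep) > 0, "pcoa: no positive eigenvalue")
  coords <- sc$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = eig[keep],
                 n_imputed = n_imputed),
            class = "pcoa_result")
}

#' Procrustes alignment of a configuration onto geography
#'
#' Least-squares orthogonal Procrustes: translation, uniform scaling and
#' rotation/reflection of `config` minimizing the sum of squared
#' differences to `target` (e.g. island longitude/latitude). Wraps
#' [vegan::procrustes()] with symmetric scaling disabled so the aligned
#' configuration lives in the target's coordinate system.
#'
#' @param config matrix of ordination coordinates (rows = areas).
#' @param target matrix of target coordinates, same rows in the same
#'   order, at least 3 rows.
#' @return List of class `procrustes_result`: `aligned` coordinates,
#'   `residual_ss` (sum of squared residuals), `rotation`, `scale`,
#'   `translation`.
#' @export
procrustes_align <- function(config, target) {
  config <- as.matrix(config); target <- as.matrix(target)
  .assert(nrow(config) == nrow(target), "row count mismatch")
  .assert(nrow(config) >= 3, "need >= 3 rows for Procrustes")
  k <- min(ncol(config), ncol(target))
  pr <- vegan::procrustes(X = target[, seq_len(k), drop = FALSE],
                          Y = config[, seq_len(k), drop = FALSE],
                          scale = TRUE, symmetric = FALSE)
  # vegan returns the rotated configuration centred at the origin;
  # shift it back onto the target's centroid
  aligned <- sweep(pr$Yrot, 2, as.numeric(pr$xmean), `+`)
  rownames(aligned) <- rownames(config)
  structure(list(aligned = aligned, residual_ss = pr$ss,
                 rotation = pr$rotation, scale = pr$scale,
                 translation = pr$translation),
            class = "procrustes_result")
}

#' Project an ordination onto RGB colours
#'
#' Min-max scales the first axis to the red channel and the second to
#' the green channel; blue is `255 - round((r + g) / 2)`. A constant
#' axis maps to a fixed 128 (warned). Areas with identical coordinates
#' receive identical colours, and colour distance grows with
#' configuration distance.
#'
#' @param coords matrix of coordinates (>= 1 column; first two used).
#' @return Integer matrix with columns `r`, `g`, `b` in `[0, 255]`, one
#'   row per area.
#' @export
rgb_project <- function(coords) {
  coords <- as.matrix(coords)
  .assert(ncol(coords) >= 1, "rgb_project: need at least one axis")
  channel <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("rgb_project: constant axis mapped to 128")
      return(rep(128L, length(x)))
    }
    as.integer(round(255 * (x - rng[1]) / diff(rng)))
  }
  r <- channel(coords[, 1])
  g <- if (ncol(coords) >= 2) channel(coords[, 2]) else rep(128L, nrow(coords))
  b <- 255L - as.integer(round((r + g) / 2))
  out <- cbind(r = r, g = g, b = b)
  rownames(out) <- rownames(coords)
  out
}
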