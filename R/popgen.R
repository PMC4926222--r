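# Distance-based population differentiation per species unit.
#
# Ht = mean p-distance over all specimen pairs of a unit (total
# diversity); Hs = unweighted mean of the within-area mean p-distances
# (areas with a single specimen are excluded from Hs but their specimens
# still enter Ht); Dst = Ht - Hs (negative values clamped to zero, the
# standard treatment of small-sample bias); Gst = Dst / Ht in [0, 1].
# Pairwise-area Gst uses the Nei decomposition restricted to the two
# areas, standardized by the species-wide Ht.

.mean_pairwise <- function(d, idx) {
  if (length(idx) < 2) return(NA_real_)
  sub <- d[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Total diversity Ht of one species unit
#'
#' Unweighted mean p-distance over all unordered specimen pairs.
#'
#' @param d symmetric p-distance matrix of the unit's specimens (from
#'   [p_distance_matrix()]).
#' @return Ht, or an error with fewer than 2 specimens.
#' @export
diversity_total <- function(d) {
  .assert(nrow(d) >= 2, "diversity_total: need >= 2 specimens")
  mean(d[upper.tri(d)])
}

#' Within-area diversity Hs of one species unit
#'
#' For each area with at least 2 specimens, the mean within-area pairwise
#' p-distance; Hs is the unweighted mean across those areas.
#'
#' @param d symmetric p-distance matrix of the unit's specimens.
#' @param areas area label per specimen (same order as `d`).
#' @return Hs, or `NA` when no area has 2+ specimens.
#' @export
diversity_within <- function(d, areas) {
  .assert(length(areas) == nrow(d), "areas must match distance matrix rows")
  by_area <- split(seq_along(areas), areas)
  vals <- vapply(by_area, function(idx) .mean_pairwise(d, idx), numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Dst and Gst from Ht and Hs
#'
#' `Dst_raw = Ht - Hs`; negative values (within-area diversity exceeding
#' total, a small-sample artefact) are clamped to zero. `Gst = Dst / Ht`
#' when `Ht > 0`, else 0 by convention.
#'
#' @param ht,hs total and within-area diversities.
#' @return List with `dst_raw`, `dst`, `gst`, `clamped` (logical).
#' @export
dst_gst <- function(ht, hs) {
  .assert(is.finite(ht) && is.finite(hs), "dst_gst: Ht and Hs must be defined")
  dst_raw <- ht - hs
  clamped <- dst_raw < 0
  dst <- max(dst_raw, 0)
  gst <- if (ht > 0) dst / ht else 0
  list(dst_raw = dst_raw, dst = dst, gst = gst, clamped = clamped)
}

#' Pairwise-area Gst for one species unit
#'
#' Restricted to areas `i` and `j`: `Ht_ij` is the mean pairwise
#' p-distance over the pooled specimens of the two areas, `Hs_ij` the
#' unweighted mean of the two within-area means, and
#' `Gst_ij = max(Ht_ij - Hs_ij, 0) / Ht`, standardized by the
#' species-wide total diversity `Ht`. Requires 2+ specimens per area.
#'
#' @param d p-distance matrix of the unit's specimens.
#' @param areas area label per specimen.
#' @param area_i,area_j the two area labels.
#' @param ht species-wide total diversity (from [diversity_total()]).
#' @return `Gst_ij` in `[0, 1]`, or `NA` if either area has < 2
#'   specimens.
#' @export
pairwise_gst <- function(d, areas, area_i, area_j, ht) {
  ii <- which(areas == area_i)
  jj <- which(areas == area_j)
  if (length(ii) < 2 || length(jj) < 2) return(NA_real_)
  ht_ij <- .mean_pairwise(d, c(ii, jj))
  hs_ij <- mean(c(.mean_pairwise(d, ii), .mean_pairwise(d, jj)))
  dst_ij <- max(ht_ij - hs_ij, 0)
  if (ht > 0) dst_ij / ht else 0
}

#' Differentiation statistics for every species unit
#'
#' Computes Ht, Hs, raw and clamped Dst, Gst and the full area x area
#' pairwise Gst matrix per unit. Units with fewer than 2 specimens, or
#' with no area holding 2+ specimens, are skipped with a message.
#'
#' @param seqs a [sequence_set()].
#' @param units unit assignment from [cluster_units()]; defaults to one
#'   unit per `species_label`.
#' @param areas optional ordered vector of area labels for the pairwise
#'   matrices (default: areas present in `seqs`).
#' @return A list of class `diff_stats`: per unit `ht`, `hs`, `dst_raw`,
#'   `dst`, `gst`, `clamped`, `n_per_area`, `pairwise_gst` matrix.
#' @export
diff_stats <- function(seqs, units = NULL, areas = NULL) {
  stopifnot(inherits(seqs, "sequence_set"))
  unit_of <- if (is.null(units)) seqs$species_label else
    units$unit_id[match(seqs$specimen_id, units$specimen_id)]
  if (is.null(areas)) areas <- unique(seqs$area_label)
  out <- list()
  for (u in unique(unit_of)) {
    idx <- which(unit_of == u)
    if (length(idx) < 2) {
      message(sprintf("diff_stats: unit %s skipped (<2 specimens)", u))
      next
    }
    sub <- seqs[idx, , drop = FALSE]
    d <- p_distance_matrix(sub$sequence)
    ht <- diversity_total(d)
    hs <- diversity_within(d, sub$area_label)
    if (is.na(hs)) {
      message(sprintf("diff_stats: unit %s skipped (no area with 2+ specimens)", u))
      next
    }
    dg <- dst_gst(ht, hs)
    if (dg$clamped) message(sprintf("diff_stats: unit %s Dst clamped to 0", u))
    pw <- matrix(NA_real_, length(areas), length(areas),
                 dimnames = list(areas, areas))
    for (i in seq_along(areas)) {
      for (j in seq_along(areas)) {
        if (i < j) {
          pw[i, j] <- pw[j, i] <-
            pairwise_gst(d, sub$area_label, areas[i], areas[j], ht)
        }
      }
    }
    out[[u]] <- list(unit_id = u, ht = ht, hs = hs, dst_raw = dg$dst_raw,
                     dst = dg$dst, gst = dg$gst, clamped = dg$clamped,
                     n_per_area = table(factor(sub$area_label, levels = areas)),
                     pairwise_gst = pw)
  }
  class(out) <- "diff_stats"
  out
}

#' Mean Gst matrix across species units
#'
#' Cell-wise arithmetic mean of the available pairwise Gst values over
#' all units; cells with no contributing unit are `NA` (warned).
#'
#' @param stats a `diff_stats` list from [diff_stats()].
#' @return List with `mean_gst` (symmetric area x area matrix) and
#'   `n_units` (contributing units per cell).
#' @export
mean_gst_matrix <- function(stats) {
  .assert(length(stats) >= 1, "mean_gst_matrix: need at least one unit")
  mats <- lapply(stats, `[[`, "pairwise_gst")
  areas <- rownames(mats[[1]])
  arr <- simplify2array(mats)
  mean_gst <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  n_units <- apply(arr, c(1, 2), function(v) sum(!is.na(v)))
  diag(mean_gst) <- NA_real_
  off <- mean_gst[upper.tri(mean_gst)]
  if (anyNA(off)) {
    warning(sprintf("mean_gst_matrix: %d cells with no contributing unit",
                    sum(is.na(off))))
  }
  list(mean_gst = mean_gst, n_units = n_units)
}

#' Mean Dst per area
#'
#' Unweighted mean of the unit Dst values over the units occurring in
#' each area (an area hosts a unit when at least one of its specimens
#' was sampled there). Areas hosting no unit are `NA`.
#'
#' @param stats a `diff_stats` list.
#' @return Named numeric vector of mean Dst per area.
#' @export
mean_dst_per_area <- function(stats) {
  .assert(length(stats) >= 1, "mean_dst_per_area: need at least one unit")
  areas <- names(stats[[1]]$n_per_area)
  vapply(areas, function(a) {
    dsts <- vapply(stats, function(s) {
      if (s$n_per_area[[a]] > 0) s$dst else NA_real_
    }, numeric(1))
    dsts <- dsts[!is.na(dsts)]
    if (length(dsts)) mean(dsts) else NA_real_
  }, numeric(1))
}

#' Filter areas by sequencing coverage of the recorded fauna
#'
#' Retains areas where the sequenced fraction of the recorded fauna is
#' strictly greater than `threshold`; exclusions are logged.
#'
#' @param sequenced named vector, species sequenced per area.
#' @param recorded named vector, species recorded per area.
#' @param threshold coverage threshold, default 0.8.
#' @return Character vector of retained area names.
#' @export
coverage_filter <- function(sequenced, recorded, threshold = 0.8) {
  .assert(all(names(sequenced) == names(recorded)),
          "sequenced and recorded must cover the same areas in order")
  .assert(all(recorded > 0), "coverage_filter: area with zero recorded species")
  frac <- sequenced / recorded
  keep <- frac > threshold
  if (any(!keep)) {
    message("coverage_filter: excluded ",
            paste(sprintf("%s (%.1f%%)", names(frac)[!keep], 100 * frac[!keep]),
                  collapse = ", "))
  }
  if (!any(keep)) warning("coverage_filter: no area passes the coverage threshold")
  names(frac)[keep]
}
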