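# Species-unit delimitation from COI barcodes: uncorrected p-distances
# with pairwise deletion of missing sites, and single-linkage clustering
# at a 3% threshold (connected components of the "< threshold" graph).

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among comparable sites. Sites where
#' either sequence carries `N` or a gap are excluded (pairwise deletion).
#'
#' @param a,b character scalars, equal length, alphabet `A,C,G,T,N,-`.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  .assert(nchar(a) == nchar(b), "p_distance: sequences must have equal length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ok <- ca %in% .bases & cb %in% .bases
  n_ok <- sum(ok)
  if (n_ok == 0) {
    stop("p_distance: no comparable sites (all masked by N or gaps)", call. = FALSE)
  }
  sum(ca[ok] != cb[ok]) / n_ok
}

# Integer-encode sequences for fast pairwise comparison; 0 = missing.
.encode_seqs <- function(sequences) {
  lapply(strsplit(toupper(sequences), ""), function(ch) {
    code <- match(ch, .bases)
    code[is.na(code)] <- 0L
    code
  })
}

#' Pairwise p-distance matrix
#'
#' Computes all pairwise uncorrected p-distances for a sequence set.
#' Pairs of unequal length, or with no comparable site, get `NA`.
#'
#' @param seqs a [sequence_set()] (or character vector of sequences).
#' @return Symmetric numeric matrix with zero diagonal; dimnames are
#'   specimen ids when available.
#' @export
p_distance_matrix <- function(seqs) {
  sequences <- if (inherits(seqs, "sequence_set")) seqs$sequence else seqs
  ids <- if (inherits(seqs, "sequence_set")) seqs$specimen_id else names(seqs)
  n <- length(sequences)
  enc <- .encode_seqs(sequences)
  len <- nchar(sequences)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (len[i] != len[j]) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      ok <- enc[[i]] > 0L & enc[[j]] > 0L
      n_ok <- sum(ok)
      d[i, j] <- d[j, i] <- if (n_ok == 0) NA_real_ else
        sum(enc[[i]][ok] != enc[[j]][ok]) / n_ok
    }
  }
  d
}

#' Cluster specimens into species units at a p-distance threshold
#'
#' Single-linkage clustering: two specimens belong to the same unit iff a
#' chain of pairwise p-distances strictly below `threshold` connects
#' them (connected components of the "< threshold" graph). Undefined
#' distances (unequal lengths, no comparable sites) never link and are
#' logged. Unit ids are `<smallest member species_label>_<k>`, with `k`
#' counting units sharing that label in order of first appearance.
#'
#' @param seqs a [sequence_set()].
#' @param threshold linking threshold, default 0.03 (the 3\% barcode
#'   rule-of-thumb separating most Lepidoptera sister species).
#' @return A data frame with one row per specimen: `specimen_id`,
#'   `unit_id`, `species_label`, `area_label`; `units` attribute lists
#'   member ids per unit.
#' @export
cluster_units <- function(seqs, threshold = 0.03) {
  stopifnot(inherits(seqs, "sequence_set"))
  d <- p_distance_matrix(seqs)
  n_na <- sum(is.na(d[upper.tri(d)]))
  if (n_na > 0) {
    message(sprintf("cluster_units: %d undefined pairwise distances treated as unlinked", n_na))
  }
  adj <- !is.na(d) & d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable unit ordering: by first specimen appearance
  comp_order <- unique(comp)
  label_count <- list()
  unit_id <- character(length(comp_order))
  names(unit_id) <- as.character(comp_order)
  for (cid in comp_order) {
    members <- which(comp == cid)
    lab <- min(seqs$species_label[members])
    k <- (label_count[[lab]] %||% 0L) + 1L
    label_count[[lab]] <- k
    unit_id[as.character(cid)] <- paste0(lab, "_", k)
  }
  out <- data.frame(specimen_id = seqs$specimen_id,
                    unit_id = unname(unit_id[as.character(comp)]),
                    species_label = seqs$species_label,
                    area_label = seqs$area_label,
                    stringsAsFactors = FALSE)
  attr(out, "units") <- split(out$specimen_id, out$unit_id)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
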