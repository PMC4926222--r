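# Independent brute-force oracles and small fixture builders shared by
# the tests. Everything here deliberately avoids the package's own
# vectorized code paths.

# NODF by naive pair enumeration on the packed matrix.
nodf_oracle <- function(m) {
  m <- unclass(m)
  m <- m[order(-rowSums(m)), order(-colSums(m)), drop = FALSE]
  total <- 0
  np <- 0
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      np <- np + 1
      fi <- sum(m[i, ]); fj <- sum(m[j, ])
      if (fi > fj && fj > 0) {
        total <- total + 100 * sum(m[i, ] == 1 & m[j, ] == 1) / fj
      }
    }
  }
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      np <- np + 1
      fi <- sum(m[, i]); fj <- sum(m[, j])
      if (fi > fj && fj > 0) {
        total <- total + 100 * sum(m[, i] == 1 & m[, j] == 1) / fj
      }
    }
  }
  total / np
}

# Connected components of the "< threshold" graph by breadth-first
# search on the distance matrix (no igraph).
components_oracle <- function(d, threshold) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(!is.na(d[v, ]) & d[v, ] < threshold & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# lmg by direct enumeration of all predictor orderings.
lmg_orderings_oracle <- function(data, yname, preds) {
  r2 <- function(sub) {
    f <- if (length(sub)) paste(yname, "~", paste(sub, collapse = "+")) else
      paste(yname, "~ 1")
    summary(lm(as.formula(f), data = data))$r.squared
  }
  perms <- combinat_perms(preds)
  shares <- setNames(numeric(length(preds)), preds)
  for (ord in perms) {
    prev <- character(0)
    for (x in ord) {
      shares[x] <- shares[x] + r2(c(prev, x)) - r2(prev)
      prev <- c(prev, x)
    }
  }
  shares / length(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Random small binary matrix guaranteed non-degenerate for NODF.
random_incidence <- function(nr, nc, p = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (sum(m) > 0) return(incidence_matrix(m))
  }
}

# A sequence set where two areas are fixed for haplotypes differing at
# `ndiff` of `len` sites (the canonical 2+2 fixed-difference unit).
fixed_difference_set <- function(ndiff = 10, len = 600, n_per_area = 2,
                                 species = "spA") {
  h1 <- strrep("A", len)
  h2 <- paste0(strrep("C", ndiff), strrep("A", len - ndiff))
  sequence_set(
    specimen_id = sprintf("%s_%d", species, seq_len(2 * n_per_area)),
    species_label = rep(species, 2 * n_per_area),
    area_label = rep(c("north", "south"), each = n_per_area),
    sequence = rep(c(h1, h2), each = n_per_area)
  )
}

# Enumerate every binary matrix with the row/column sums of `m`
# (brute force over all 0/1 matrices of that size; feasible up to 4x4).
enumerate_fixed_marginals <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- rowSums(m); cs <- colSums(m)
  states <- character(0)
  for (code in 0:(2^(nr * nc) - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(nr * nc)])
    cand <- matrix(bits, nr, nc)
    if (all(rowSums(cand) == rs) && all(colSums(cand) == cs)) {
      states <- c(states, paste(bits, collapse = ""))
    }
  }
  states
}

matrix_key <- function(m) paste(as.integer(unclass(m)), collapse = "")
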