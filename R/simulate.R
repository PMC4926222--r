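# Synthetic archipelago generators: incidence matrices with a tunable
# nestedness-vs-turnover balance, multi-lineage haplotype sets with
# controlled inter-area divergence, and covariate tables from a known
# linear model. One global seed governs reproducible per-species /
# per-island sub-streams, so enlarging the community does not perturb
# earlier draws.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the three generators.
#'
#' @param seed integer master seed; every generator derives deterministic
#'   sub-streams from it.
#' @param n_islands,n_species dimensions of the simulated incidence
#'   matrix (both >= 2).
#' @param nestedness_weight in `[0,1]`; 1 = purely nested occupancy
#'   gradients, 0 = pure block turnover.
#' @param gradient_strength half-range of the species propensity and
#'   island suitability gradients on the logit scale (default 4,
#'   a moderately nested community; around 10 the Bernoulli draws are
#'   nearly deterministic and the matrix approaches perfect nestedness).
#' @param n_blocks number of disjoint turnover blocks (species assigned
#'   round-robin to island groups).
#' @param n_areas number of genetic sampling areas (>= 2).
#' @param n_per_area specimens sequenced per species per area.
#' @param lineage_divergence fixed inter-lineage divergence in
#'   substitutions per site, in `[0, 0.2]`; two lineages per species.
#' @param within_lineage_theta expected number of private mutations per
#'   specimen (Poisson).
#' @param chequered if `TRUE`, the two lineages are assigned to disjoint
#'   area groups (mutual spatial exclusion); if `FALSE`, lineage
#'   membership is mixed within areas.
#' @param seq_length sequence length in bp (COI barcode convention, 658).
#' @param richness_coefficients named vector `b0, b_IA, b_EL, b_IS,
#'   b_SR, b_PC` of the generating model for `log10(richness)`.
#' @param noise_sd residual standard deviation of the generating model,
#'   on the log10 scale.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_islands = 11L,
                       n_species = 27L,
                       nestedness_weight = 0.7,
                       gradient_strength = 4,
                       n_blocks = 2L,
                       n_areas = 4L,
                       n_per_area = 4L,
                       lineage_divergence = 0.04,
                       within_lineage_theta = 0.5,
                       chequered = TRUE,
                       seq_length = 658L,
                       richness_coefficients = c(b0 = 0.2, b_IA = 0.25,
                                                 b_EL = 2e-4, b_IS = -0.15,
                                                 b_SR = 0.4, b_PC = 0.15),
                       noise_sd = 0.05) {
  .assert(n_islands >= 2 && n_species >= 2 && n_areas >= 2 && n_per_area >= 2,
          "all counts must be >= 2")
  .assert(nestedness_weight >= 0 && nestedness_weight <= 1,
          "nestedness_weight must be in [0,1]")
  .assert(lineage_divergence >= 0 && lineage_divergence <= 0.2,
          "lineage_divergence must be in [0, 0.2]")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  need <- c("b0", "b_IA", "b_EL", "b_IS", "b_SR", "b_PC")
  .assert(all(need %in% names(richness_coefficients)),
          paste("richness_coefficients needs:", paste(need, collapse = ", ")))
  structure(list(seed = as.integer(seed), n_islands = as.integer(n_islands),
                 n_species = as.integer(n_species),
                 nestedness_weight = nestedness_weight,
                 gradient_strength = gradient_strength,
                 n_blocks = as.integer(n_blocks),
                 n_areas = as.integer(n_areas),
                 n_per_area = as.integer(n_per_area),
                 lineage_divergence = lineage_divergence,
                 within_lineage_theta = within_lineage_theta,
                 chequered = isTRUE(chequered),
                 seq_length = as.integer(seq_length),
                 richness_coefficients = richness_coefficients[need],
                 noise_sd = noise_sd),
            class = "sim_config")
}

#' Simulate a presence-absence incidence matrix
#'
#' Presence probability interpolates between a nested occupancy gradient
#' and block turnover:
#' `p(i,s) = w * plogis(alpha_s + beta_i) + (1 - w) * turnover(i,s)`,
#' where `alpha_s` is a species incidence propensity decreasing in `s`,
#' `beta_i` an island suitability decreasing in `i`, and the turnover
#' term is 1 when species `s`'s block (round-robin over `n_blocks`)
#' matches island `i`'s group and 0 otherwise. Cells are independent
#' Bernoulli draws; all-zero matrices are resampled (up to 100 times).
#'
#' @param config a [sim_config()].
#' @return An [incidence_matrix()] of dimension `n_islands x n_species`.
#' @export
simulate_incidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$nestedness_weight
  ni <- config$n_islands
  ns <- config$n_species
  g <- config$gradient_strength
  alpha <- seq(g, -g, length.out = ns)     # species propensity gradient
  beta <- seq(g, -g, length.out = ni)      # island suitability gradient
  p_nest <- outer(beta, alpha, function(b, a) stats::plogis(a + b))
  sp_block <- (seq_len(ns) - 1L) %% config$n_blocks
  isl_group <- (seq_len(ni) - 1L) %% config$n_blocks
  p_turn <- outer(isl_group, sp_block, function(i, s) as.numeric(i == s))
  p <- w * p_nest + (1 - w) * p_turn
  set.seed(.substream_seed(config$seed, 1L))
  for (attempt in seq_len(100L)) {
    cells <- matrix(rbinom(ni * ns, 1L, p), ni, ns)
    if (sum(cells) > 0) {
      return(incidence_matrix(cells,
                              islands = sprintf("island_%02d", seq_len(ni)),
                              species = sprintf("sp_%02d", seq_len(ns))))
    }
  }
  stop("simulate_incidence: all draws degenerate (all-zero matrix)", call. = FALSE)
}

.bases <- c("A", "C", "G", "T")

#' Simulate multi-lineage COI haplotype sets
#'
#' Per species: a random base sequence of `seq_length` bp; two lineages
#' separated by `round(seq_length * lineage_divergence)` fixed
#' differences; lineages assigned to areas either disjointly
#' (`chequered = TRUE`: first half of the areas carries lineage A, the
#' rest lineage B) or mixed (each specimen draws its lineage at random);
#' finally `Poisson(within_lineage_theta)` private mutations per
#' specimen.
#'
#' @param config a [sim_config()].
#' @return A [sequence_set()] with `n_species * n_areas * n_per_area`
#'   records.
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$seq_length
  n_fixed <- round(L * config$lineage_divergence)
  if (config$chequered && n_fixed < 1) {
    warning("lineage_divergence * seq_length < 1: chequered lineages are indistinguishable")
  }
  areas <- sprintf("area_%02d", seq_len(config$n_areas))
  group_a <- seq_len(ceiling(config$n_areas / 2))
  recs <- vector("list", config$n_species)
  for (s in seq_len(config$n_species)) {
    set.seed(.substream_seed(config$seed, 1000L + s))
    base <- sample(.bases, L, replace = TRUE)
    diff_sites <- sample.int(L, n_fixed)
    lineage_b <- base
    for (site in diff_sites) {
      lineage_b[site] <- sample(setdiff(.bases, base[site]), 1L)
    }
    sp <- sprintf("sp_%02d", s)
    ids <- character(0); labs <- character(0); seqs <- character(0)
    for (a in seq_len(config$n_areas)) {
      for (k in seq_len(config$n_per_area)) {
        if (config$chequered) {
          hap <- if (a %in% group_a) base else lineage_b
        } else {
          hap <- if (sample(c(TRUE, FALSE), 1L)) base else lineage_b
        }
        n_priv <- rpois(1L, config$within_lineage_theta)
        if (n_priv > 0) {
          sites <- sample.int(L, min(n_priv, L))
          for (site in sites) {
            hap[site] <- sample(setdiff(.bases, hap[site]), 1L)
          }
        }
        ids <- c(ids, sprintf("%s_%s_%02d", sp, areas[a], k))
        labs <- c(labs, areas[a])
        seqs <- c(seqs, paste(hap, collapse = ""))
      }
    }
    recs[[s]] <- data.frame(specimen_id = ids, species_label = sp,
                            area_label = labs, sequence = seqs,
                            stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, recs)
  sequence_set(all$specimen_id, all$species_label, all$area_label, all$sequence)
}

#' Simulate island covariates from a known richness model
#'
#' Draws island area `IA` log-uniform on `[1, 1000]` km^2, elevation `EL`
#' uniform on `[50, 1500]` m, isolation `IS` log-uniform on `[1, 200]`
#' km, source richness `SR` uniform on `{50, ..., 250}` species, and a
#' Pleistocene connection `PC ~ Bernoulli(0.3)`. Richness follows
#' `log10(richness) = b0 + b_IA*log10(IA) + b_EL*EL + b_IS*log10(IS) +
#' b_SR*log10(SR) + b_PC*PC + N(0, noise_sd)`, back-transformed and
#' rounded (floor 1 species). `MT` and `AP` are decoy climate predictors
#' with zero true effect.
#'
#' @param config a [sim_config()].
#' @return A [covariate_table()] with `n_islands` rows.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  b <- config$richness_coefficients
  ni <- config$n_islands
  set.seed(.substream_seed(config$seed, 2L))
  IA <- 10^runif(ni, 0, 3)
  EL <- runif(ni, 50, 1500)
  IS <- 10^runif(ni, 0, log10(200))
  SR <- round(runif(ni, 50, 250))
  PC <- rbinom(ni, 1L, 0.3)
  MT <- runif(ni, 12, 20)         # decoys: no effect on richness
  AP <- runif(ni, 300, 900)
  log_rich <- b["b0"] + b["b_IA"] * log10(IA) + b["b_EL"] * EL +
    b["b_IS"] * log10(IS) + b["b_SR"] * log10(SR) + b["b_PC"] * PC +
    rnorm(ni, 0, config$noise_sd)
  richness <- pmax(1, round(10^log_rich))
  covariate_table(data.frame(
    island = sprintf("island_%02d", seq_len(ni)),
    MT = MT, AP = AP, IA = IA, EL = EL, IS = IS, SR = SR, PC = PC,
    richness = richness, stringsAsFactors = FALSE
  ))
}
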