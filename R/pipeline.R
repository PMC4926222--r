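# Orchestration: run every stage of the analysis from one configuration
# (units -> popgen -> community -> ordination -> occupancy tests ->
# richness), writing CSV artifacts and a JSON run report.

#' Build a run configuration
#'
#' @param fasta,incidence,covariates input paths (see [read_fasta()],
#'   [read_incidence()], [read_covariates()]). `fasta` and `covariates`
#'   may be `NULL`, skipping the genetic / richness stages.
#' @param out_dir output directory (created if absent).
#' @param seed master seed fanned out to per-stage sub-streams.
#' @param n_null null replicates for NODF and quadrant tests (>= 99).
#' @param unit_threshold p-distance threshold for species units.
#' @param coverage_threshold sequenced-fauna fraction required to retain
#'   an area.
#' @param null_models NODF null models to run.
#' @param geo optional matrix of area longitude/latitude for Procrustes.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(incidence, fasta = NULL, covariates = NULL,
                       out_dir = "islecomm_out", seed = 1L, n_null = 999L,
                       unit_threshold = 0.03, coverage_threshold = 0.8,
                       null_models = c("EE", "CE", "FF"), geo = NULL) {
  .assert(n_null >= 99, "n_null must be >= 99")
  .assert(unit_threshold > 0 && unit_threshold < 1,
          "unit_threshold must be in (0,1)")
  .assert(coverage_threshold > 0 && coverage_threshold < 1,
          "coverage_threshold must be in (0,1)")
  .assert(all(null_models %in% c("EE", "CE", "FF")), "unknown null model")
  structure(list(incidence = incidence, fasta = fasta,
                 covariates = covariates, out_dir = out_dir,
                 seed = as.integer(seed), n_null = as.integer(n_null),
                 unit_threshold = unit_threshold,
                 coverage_threshold = coverage_threshold,
                 null_models = null_models, geo = geo),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes every configured stage in order, writes the CSV artifacts to
#' `out_dir` and returns (and writes) a JSON run report. Deterministic
#' given the seed.
#'
#' @param config a [run_config()].
#' @return The run report (list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "islecomm",
                 version = as.character(utils::packageVersion("islecomm")),
                 seed = config$seed, n_null = config$n_null,
                 stages = list())
  m <- read_incidence(config$incidence)

  # community structure
  set.seed(.substream_seed(config$seed, 10L))
  nodf_rows <- list()
  parts <- c(list(all = m), {
    sw <- split_widespread_rare(m)
    list(widespread = sw$widespread, rare = sw$rare)
  })
  for (nm in names(parts)) {
    pm <- parts[[nm]]
    if (ncol(pm) < 2) next
    for (model in config$null_models) {
      res <- nodf_test(pm, model, n_null = config$n_null)
      nodf_rows[[paste(nm, model)]] <-
        data.frame(subset = nm, model = model, observed = res$observed,
                   null_mean = res$null_mean, null_sd = res$null_sd,
                   z = res$z, p = res$p, stars = res$stars)
    }
  }
  nodf_tab <- do.call(rbind, nodf_rows)
  write.csv(nodf_tab, file.path(config$out_dir, "nodf.csv"), row.names = FALSE)
  beta <- lapply(parts, function(pm) {
    if (ncol(pm) < 1) NULL else beta_partition(pm)
  })
  beta_tab <- do.call(rbind, lapply(names(beta), function(nm) {
    if (is.null(beta[[nm]])) return(NULL)
    data.frame(subset = nm,
               nest_sor_mean_of_ratios = beta[[nm]]$ratio_mean_of_ratios,
               nest_sor_ratio_of_means = beta[[nm]]$ratio_of_means,
               n_pairs = beta[[nm]]$n_pairs_used)
  }))
  write.csv(beta_tab, file.path(config$out_dir, "beta.csv"), row.names = FALSE)
  report$stages$community <- list(nodf = nodf_tab, beta = beta_tab)

  # genetic stages
  if (!is.null(config$fasta)) {
    seqs <- read_fasta(config$fasta)
    units <- cluster_units(seqs, threshold = config$unit_threshold)
    write.csv(units, file.path(config$out_dir, "units.csv"), row.names = FALSE)
    stats <- diff_stats(seqs, units)
    stat_tab <- do.call(rbind, lapply(stats, function(s) {
      data.frame(unit_id = s$unit_id, ht = s$ht, hs = s$hs,
                 dst_raw = s$dst_raw, dst = s$dst, gst = s$gst,
                 clamped = s$clamped)
    }))
    write.csv(stat_tab, file.path(config$out_dir, "diffstats.csv"),
              row.names = FALSE)
    mg <- mean_gst_matrix(stats)
    write.csv(mg$mean_gst, file.path(config$out_dir, "mean_gst.csv"))
    md <- mean_dst_per_area(stats)
    write.csv(data.frame(area = names(md), mean_dst = md),
              file.path(config$out_dir, "mean_dst.csv"), row.names = FALSE)
    report$stages$popgen <- list(n_units = length(stats),
                                 n_clamped = sum(stat_tab$clamped),
                                 mean_dst = md)

    # ordination of the mean Gst matrix
    ord <- pcoa(mg$mean_gst)
    rgb <- rgb_project(ord$coordinates)
    write.csv(data.frame(area = rownames(ord$coordinates),
                         ord$coordinates, rgb),
              file.path(config$out_dir, "ordination.csv"), row.names = FALSE)
    proc_res <- NULL
    if (!is.null(config$geo)) {
      pa <- procrustes_align(ord$coordinates, as.matrix(config$geo))
      proc_res <- pa$residual_ss
    }
    report$stages$ordination <- list(eigenvalues = ord$eigenvalues,
                                     n_imputed = ord$n_imputed,
                                     procrustes_ss = proc_res)

    # occupancy vs differentiation, for units mappable to matrix columns
    dst <- setNames(stat_tab$dst, stat_tab$unit_id)
    sp_of_unit <- vapply(strsplit(names(dst), "_(?=[0-9]+$)", perl = TRUE),
                         `[`, character(1), 1)
    mappable <- sp_of_unit %in% colnames(m) & !duplicated(sp_of_unit)
    if (sum(mappable) >= 4) {
      dst_sp <- setNames(dst[mappable], sp_of_unit[mappable])
      msub <- incidence_matrix(
        unclass(m)[, names(dst_sp), drop = FALSE])
      occ <- occupancy(msub)
      set.seed(.substream_seed(config$seed, 20L))
      sp_test <- tryCatch(spearman(occ, dst_sp), error = function(e) NULL)
      qt <- quadrant_test(occ, dst_sp, n_null = config$n_null)
      per_isl <- per_island_analysis(msub, dst_sp, n_null = config$n_null)
      write.csv(data.frame(quadrant = names(qt$observed),
                           observed = as.integer(qt$observed),
                           q = qt$q, verdict = qt$verdict),
                file.path(config$out_dir, "quadrants.csv"), row.names = FALSE)
      report$stages$occupancy <- list(spearman = sp_test,
                                      quadrant_verdicts = qt$verdict,
                                      n_islands_tested = length(per_isl))
    }
  }

  # richness models
  if (!is.null(config$covariates)) {
    cov <- read_covariates(config$covariates)
    fit_full <- stepwise_aic(cov)
    lmg <- lmg_importance(fit_full)
    rich_tab <- data.frame(predictor = rownames(fit_full$coefficients),
                           fit_full$coefficients,
                           check.names = FALSE)
    write.csv(rich_tab, file.path(config$out_dir, "richness.csv"),
              row.names = FALSE)
    lgm_isl <- cov$island[cov$PC == 1]
    lgm <- NULL
    if (length(lgm_isl) && "PC" %in% sub("log_", "", fit_full$predictors)) {
      no_pc <- setdiff(sub("log_", "", fit_full$predictors), "PC")
      fit1 <- fit_richness(cov, no_pc)
      lgm <- lgm_estimate(fit1, fit_full, lgm_isl)
      write.csv(lgm, file.path(config$out_dir, "lgm.csv"), row.names = FALSE)
    }
    report$stages$richness <- list(
      selected = fit_full$predictors, r_squared = fit_full$r_squared,
      lmg_percent = 100 * lmg, lgm = lgm)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}
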