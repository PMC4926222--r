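# Ht/Hs/Dst/Gst per species unit and the area-level aggregations.

test_that("total and within-area diversity match hand enumeration", {
  # 2+2 specimens fixed for haplotypes differing at 10 of 600 sites:
  # 4 cross pairs at 10/600 plus 2 identical within pairs over 6 pairs
  ss <- fixed_difference_set(ndiff = 10, len = 600)
  d <- p_distance_matrix(ss)
  ht <- diversity_total(d)
  hs <- diversity_within(d, ss$area_label)
  expect_equal(ht, (4 * (10 / 600)) / 6)
  expect_equal(hs, 0)
  dg <- dst_gst(ht, hs)
  expect_equal(dg$dst, ht)
  expect_equal(dg$gst, 1)
})

test_that("Hs averages per-area means without weighting by sample size", {
  L <- 100
  s1 <- strrep("A", L)
  s2 <- paste0("C", strrep("A", L - 1))          # 0.01 from s1
  s3 <- paste0("CG", strrep("A", L - 2))         # 0.02 from s1, 0.01 from s2
  ss <- sequence_set(c("a1", "a2", "a3", "b1", "b2"),
                     rep("sp", 5),
                     c("area1", "area1", "area1", "area2", "area2"),
                     c(s1, s2, s3, s1, s1))
  d <- p_distance_matrix(ss)
  hs <- diversity_within(d, ss$area_label)
  expect_equal(hs, mean(c(mean(c(0.01, 0.02, 0.01)), 0)))
})

test_that("a single sampled area gives Hs = Ht and Dst = 0", {
  ss <- sequence_set(c("a", "b", "c"), rep("sp", 3), rep("one", 3),
                     c(strrep("A", 50),
                       paste0("C", strrep("A", 49)),
                       paste0("CC", strrep("A", 48))))
  d <- p_distance_matrix(ss)
  ht <- diversity_total(d)
  hs <- diversity_within(d, ss$area_label)
  expect_equal(hs, ht)
  expect_equal(dst_gst(ht, hs)$dst, 0)
})

test_that("negative raw Dst is clamped to zero and flagged", {
  # both areas polymorphic for the same two distant haplotypes:
  # within-area diversity (1) exceeds total (2/3)
  h1 <- strrep("A", 30); h2 <- strrep("C", 30)
  ss <- sequence_set(c("n1", "n2", "s1", "s2"), rep("sp", 4),
                     c("north", "north", "south", "south"),
                     c(h1, h2, h1, h2))
  d <- p_distance_matrix(ss)
  ht <- diversity_total(d)
  hs <- diversity_within(d, ss$area_label)
  expect_gt(hs, ht)
  dg <- dst_gst(ht, hs)
  expect_true(dg$clamped)
  expect_lt(dg$dst_raw, 0)
  expect_equal(dg$dst, 0)
  expect_equal(dg$gst, 0)
})

test_that("monomorphic units give (Dst, Gst) = (0, 0)", {
  dg <- dst_gst(0, 0)
  expect_equal(c(dg$dst, dg$gst), c(0, 0))
})

test_that("pairwise Gst hits its fixed-difference and identity limits", {
  ss <- fixed_difference_set()
  d <- p_distance_matrix(ss)
  ht <- diversity_total(d)
  expect_equal(pairwise_gst(d, ss$area_label, "north", "south", ht), 1)
  # identical composition in both areas
  h <- strrep("A", 30)
  ss2 <- sequence_set(paste0("s", 1:4), rep("sp", 4),
                      c("x", "x", "y", "y"), rep(h, 4))
  d2 <- p_distance_matrix(ss2)
  expect_equal(pairwise_gst(d2, ss2$area_label, "x", "y", 0), 0)
  # single-specimen area: undefined
  expect_true(is.na(pairwise_gst(d, c("north", "north", "south", "only1"),
                                 "south", "only1", ht)))
})

test_that("pairwise Gst matches an independent enumeration on 3 areas", {
  cfg <- sim_config(seed = 41, n_species = 2, n_areas = 3, n_per_area = 3,
                    lineage_divergence = 0.02, within_lineage_theta = 1,
                    chequered = TRUE)
  ss_all <- simulate_sequences(cfg)
  ss <- sequence_set(ss_all$specimen_id[ss_all$species_label == "sp_01"],
                     ss_all$species_label[ss_all$species_label == "sp_01"],
                     ss_all$area_label[ss_all$species_label == "sp_01"],
                     ss_all$sequence[ss_all$species_label == "sp_01"])
  d <- p_distance_matrix(ss)
  ht <- diversity_total(d)
  areas <- unique(ss$area_label)
  mean_pd <- function(idx) {
    pairs <- combn(idx, 2)
    mean(vapply(seq_len(ncol(pairs)), function(k) {
      p_distance(ss$sequence[pairs[1, k]], ss$sequence[pairs[2, k]])
    }, numeric(1)))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    ii <- which(ss$area_label == areas[i])
    jj <- which(ss$area_label == areas[j])
    ht_ij <- mean_pd(c(ii, jj))
    hs_ij <- mean(c(mean_pd(ii), mean_pd(jj)))
    expect_equal(pairwise_gst(d, ss$area_label, areas[i], areas[j], ht),
                 max(ht_ij - hs_ij, 0) / ht)
  }
})

test_that("mean Gst matrix averages available cells and keeps symmetry", {
  cfg <- sim_config(seed = 7, n_species = 5, n_areas = 3, n_per_area = 3,
                    lineage_divergence = 0.02, within_lineage_theta = 1)
  st <- diff_stats(simulate_sequences(cfg))
  mg <- mean_gst_matrix(st)
  expect_true(isSymmetric(mg$mean_gst))
  # independent loop over units
  areas <- rownames(mg$mean_gst)
  for (i in 1:2) for (j in (i + 1):3) {
    vals <- vapply(st, function(s) s$pairwise_gst[areas[i], areas[j]],
                   numeric(1))
    expect_equal(mg$mean_gst[i, j], mean(vals[!is.na(vals)]))
    expect_equal(mg$n_units[i, j], sum(!is.na(vals)))
  }
  # two-unit toy case: cells 1 and 0 average to 0.5
  u1 <- st[[1]]; u2 <- st[[2]]
  u1$pairwise_gst[] <- 1; u2$pairwise_gst[] <- 0
  toy <- structure(list(a = u1, b = u2), class = "diff_stats")
  expect_equal(mean_gst_matrix(toy)$mean_gst[1, 2], 0.5)
  # input order invariance
  rev_st <- structure(rev(unclass(st)), class = "diff_stats")
  expect_equal(mean_gst_matrix(rev_st)$mean_gst, mg$mean_gst)
})

test_that("mean Dst per area averages the units hosted by each area", {
  cfg <- sim_config(seed = 9, n_species = 4, n_areas = 3, n_per_area = 3,
                    lineage_divergence = 0.02, within_lineage_theta = 1)
  st <- diff_stats(simulate_sequences(cfg))
  md <- mean_dst_per_area(st)
  dsts <- vapply(st, `[[`, numeric(1), "dst")
  expect_equal(unname(md["area_01"]), mean(dsts))  # every unit present everywhere
  # toy: an area hosting units with Dst 0.01 and 0.03 averages to 0.02
  st2 <- st[1:2]
  st2[[1]]$dst <- 0.01; st2[[2]]$dst <- 0.03
  class(st2) <- "diff_stats"
  expect_equal(unname(mean_dst_per_area(st2)["area_02"]), 0.02)
})

test_that("duplicating every specimen barely moves Ht and Hs", {
  cfg <- sim_config(seed = 3, n_species = 2, n_areas = 2, n_per_area = 6,
                    lineage_divergence = 0.02, within_lineage_theta = 2)
  ss_all <- simulate_sequences(cfg)
  keep <- ss_all$species_label == "sp_01"
  ss <- sequence_set(ss_all$specimen_id[keep], ss_all$species_label[keep],
                     ss_all$area_label[keep], ss_all$sequence[keep])
  d <- p_distance_matrix(ss)
  ht1 <- diversity_total(d)
  hs1 <- diversity_within(d, ss$area_label)
  dup <- sequence_set(c(ss$specimen_id, paste0(ss$specimen_id, "_dup")),
                      rep(ss$species_label, 2), rep(ss$area_label, 2),
                      rep(ss$sequence, 2))
  d2 <- p_distance_matrix(dup)
  n <- nrow(ss)
  expect_lt(abs(diversity_total(d2) - ht1), ht1 / n + 1e-12)
  expect_lt(abs(diversity_within(d2, dup$area_label) - hs1), hs1 / 3 + 1e-12)
})

test_that("coverage filter keeps areas strictly above the 80% threshold", {
  sequenced <- c(good = 10, exact = 8, low = 5)
  recorded <- c(good = 12, exact = 10, low = 10)
  kept <- suppressMessages(coverage_filter(sequenced, recorded))
  expect_equal(kept, "good")          # 0.833 retained; 0.80 exactly excluded
  expect_warning(suppressMessages(
    coverage_filter(c(a = 1), c(a = 10))), "no area passes")
  expect_error(coverage_filter(c(a = 1), c(a = 0)), "zero recorded")
})
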