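# NODF, null models, widespread/rare partition, beta diversity.

test_that("packing sorts marginals decreasingly and is idempotent", {
  withr::with_seed(2, {
    m <- random_incidence(5, 5)
    p <- pack_matrix(m)
    expect_true(all(diff(rowSums(p)) <= 0))
    expect_true(all(diff(colSums(p)) <= 0))
    expect_identical(pack_matrix(p), p)
    rev_m <- incidence_matrix(unclass(m)[5:1, 5:1])
    expect_identical(unname(unclass(pack_matrix(rev_m))),
                     unname(unclass(p)))
  })
})

test_that("NODF reaches 100 on perfect triangles and 0 on checkerboards", {
  tri <- incidence_matrix(outer(4:1, 1:4, function(f, j) as.integer(j <= f)))
  expect_equal(nodf(tri), 100)
  chk <- incidence_matrix(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(nodf(chk), 0)
})

test_that("NODF is invariant to row and column permutations", {
  withr::with_seed(5, {
    m <- random_incidence(7, 9)
    v <- nodf(m)
    perm <- incidence_matrix(unclass(m)[sample(7), sample(9)])
    expect_equal(nodf(perm), v)
  })
})

test_that("NODF agrees with the vegan implementation", {
  withr::with_seed(11, {
    for (k in 1:25) {
      m <- random_incidence(6, 8, p = runif(1, 0.2, 0.8))
      ref <- unname(vegan::nestednodf(unclass(m), order = TRUE)$statistic["NODF"])
      expect_equal(nodf(m), ref, tolerance = 1e-10)
    }
  })
})

test_that("EE nulls preserve total fill; FF nulls preserve both marginals", {
  withr::with_seed(3, {
    m <- random_incidence(6, 10, 0.4)
    for (k in 1:20) {
      ee <- null_matrix(m, "EE")
      expect_equal(sum(ee), sum(m))
      ff <- null_matrix(m, "FF")
      expect_equal(rowSums(ff), rowSums(m))
      expect_equal(colSums(ff), colSums(m))
    }
  })
})

test_that("CE nulls preserve marginals in expectation", {
  withr::with_seed(4, {
    m <- random_incidence(6, 10, 0.4)
    n_draw <- 1000
    rs <- matrix(0, n_draw, nrow(m))
    for (k in seq_len(n_draw)) rs[k, ] <- rowSums(null_matrix(m, "CE"))
    p <- outer(rowSums(m) / ncol(m), colSums(m) / nrow(m), `+`) / 2
    exp_rs <- rowSums(p)
    sd_rs <- sqrt(rowSums(p * (1 - p)) / n_draw)
    expect_true(all(abs(colMeans(rs) - exp_rs) < 3.5 * sd_rs))
  })
})

test_that("NODF test direction and significance behave on nested matrices", {
  hits <- vapply(1:30, function(s) {
    m <- simulate_incidence(sim_config(seed = s, nestedness_weight = 1,
                                       gradient_strength = 10))
    r <- nodf_test(m, "EE", n_null = 199, seed = s)
    r$z > 0 && r$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null sd of a degenerate matrix yields a missing z", {
  m <- incidence_matrix(matrix(1L, 3, 3))  # all nulls identical under FF
  r <- nodf_test(m, "FF", n_null = 49, seed = 1)
  expect_true(is.na(r$z))
})

test_that("widespread/rare split follows the more-than-half rule", {
  m <- matrix(0L, 11, 3)
  m[1:6, 1] <- 1L   # on 6 of 11 islands: widespread
  m[1:5, 2] <- 1L   # on 5: rare
  m[, 3] <- 1L
  sw <- split_widespread_rare(incidence_matrix(m))
  expect_equal(sw$min_islands, 6)
  expect_setequal(colnames(sw$widespread), c("sp_1", "sp_3"))
  expect_equal(colnames(sw$rare), "sp_2")
  all_on <- incidence_matrix(matrix(1L, 4, 3))
  sw2 <- suppressMessages(split_widespread_rare(all_on))
  expect_equal(ncol(sw2$rare), 0)
})

test_that("widespread species are more nested than rare ones when planted", {
  ok <- 0; valid <- 0
  for (s in 1:100) {
    m <- simulate_incidence(sim_config(seed = s, nestedness_weight = 1))
    sw <- suppressMessages(split_widespread_rare(m))
    if (ncol(sw$widespread) < 2 || ncol(sw$rare) < 2) next
    valid <- valid + 1
    if (nodf(sw$widespread) >= nodf(sw$rare)) ok <- ok + 1
  }
  expect_equal(ok, valid)
})

test_that("beta partition matches hand formulas and closes exactly", {
  # strict subset faunas: a = 3 shared, b = 2 unique, c = 0
  m <- incidence_matrix(rbind(c(1, 1, 1, 1, 1), c(1, 1, 1, 0, 0)))
  bp <- beta_partition(m)
  expect_equal(bp$bsor[1, 2], 2 / 8)
  expect_equal(bp$bsim[1, 2], 0)
  expect_equal(bp$ratio_mean_of_ratios, 1)  # pure nestedness
  # identical faunas: excluded from the ratio
  m2 <- incidence_matrix(rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1)))
  bp2 <- beta_partition(m2)
  expect_equal(bp2$bsor[1, 2], 0)
  expect_equal(bp2$n_pairs_used, 2)
  # closure and Sorensen cross-check against vegan on random matrices
  withr::with_seed(7, {
    m3 <- random_incidence(6, 12, 0.5)
    bp3 <- beta_partition(m3)
    expect_equal(bp3$bnes + bp3$bsim, bp3$bsor, tolerance = 1e-14)
    ref <- as.matrix(vegan::vegdist(unclass(m3), method = "bray",
                                    binary = TRUE))
    expect_equal(bp3$bsor[upper.tri(ref)], ref[upper.tri(ref)],
                 tolerance = 1e-12)
  })
})

test_that("empty islands are excluded from the beta ratio", {
  m <- incidence_matrix(rbind(c(1, 1, 0), c(0, 0, 0), c(1, 0, 1)))
  bp <- suppressMessages(beta_partition(m))
  expect_equal(bp$n_pairs_used, 1)
})

test_that("occupancy regression recovers planted coefficients", {
  withr::with_seed(19, {
    n <- 32
    dispersal <- runif(n)
    source_freq <- runif(n, 0, 200)
    freq <- 2 + 4 * dispersal + 0.03 * source_freq + rnorm(n, 0, 0.5)
    reg <- occupancy_regression(freq, dispersal, source_freq)
    co <- reg$coefficients
    expect_lt(abs(co["dispersal", 1] - 4), 2 * co["dispersal", 2])
    expect_lt(abs(co["source", 1] - 0.03), 2 * co["source", 2])
    expect_equal(sum(reg$lmg), reg$r_squared, tolerance = 1e-10)
  })
})

test_that("orthogonal predictors take lmg shares equal to marginal r^2", {
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), times = 8)
  withr::with_seed(23, {
    y <- 2 * x1 + 0.5 * x2 + rnorm(16, 0, 0.3)
    reg <- occupancy_regression(y, x1, x2)
    expect_equal(unname(reg$lmg["dispersal"]), cor(y, x1)^2, tolerance = 1e-10)
    expect_equal(unname(reg$lmg["source"]), cor(y, x2)^2, tolerance = 1e-10)
  })
})
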