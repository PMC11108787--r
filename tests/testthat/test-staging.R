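test_that("threshold derivation reproduces the constructed fixture exactly", {
  fx <- synthetic_map_fixture()
  thr <- derive_thresholds(fx, "hippocampus_tangle_density",
                           region_conditioning_stage = 2L)
  expect_equal(thr$lc_max_at_braak0, 0.379)
  expect_equal(thr$lc_cutoff_mean, 0.143)
  expect_equal(thr$region_max_at_prior_stage, 7.91)
  expect_equal(thr$region_cutoff_mean, 2.757)
  expect_true(thr$lc_cutoff_ci[1] <= 0.143 && 0.143 <= thr$lc_cutoff_ci[2])
})

test_that("degenerate and hand-computed threshold cases", {
  const <- data.frame(group = rep("unimpaired", 4), braak = c(0, 0, 1, 2),
                      lc_tangle_density = rep(0.2, 4),
                      hippocampus_tangle_density = rep(3, 4))
  # all-equal densities: the strictly-below step has an empty set
  expect_error(derive_thresholds(const, "hippocampus_tangle_density"),
               "fewer than 2")

  tab <- data.frame(group = c(rep("unimpaired", 6), "impaired"),
                    braak = c(0, 0, 0, 0, 0, 0, 3),
                    lc_tangle_density = c(.1, .2, .3, .15, .25, .9, .5),
                    hippocampus_tangle_density = c(1, 2, 3, 4, 5, 6, 9))
  thr <- derive_thresholds(tab, "hippocampus_tangle_density")
  # spreadsheet t-interval over the five LC values below max 0.9
  v <- c(.1, .2, .3, .15, .25)
  expect_equal(thr$lc_cutoff_mean, mean(v))
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(thr$lc_cutoff_ci, c(mean(v) - half, mean(v) + half))
  expect_equal(unname(thr$n_used["lc_mean"]), 5L)

  # row order never matters
  thr_shuffled <- derive_thresholds(tab[sample(nrow(tab)), ],
                                    "hippocampus_tangle_density")
  expect_equal(thr_shuffled, thr)

  expect_error(derive_thresholds(tab, "no_such_region"), "no column")
  none <- tab; none$braak <- 5
  expect_error(derive_thresholds(none, "hippocampus_tangle_density"),
               "empty conditioning")
})

test_that("classification uses strict inequalities and tallies everyone", {
  thr <- structure(list(region = "hippocampus_tangle_density",
                        lc_cutoff_mean = 0.143, lc_cutoff_ci = c(.05, .24),
                        region_cutoff_mean = 2.757,
                        region_cutoff_ci = c(2.0, 3.5)),
                   class = "staging_thresholds")
  tab <- data.frame(
    lc_tangle_density = c(0.2, 0.143, 0.1, 0.5),
    hippocampus_tangle_density = c(1.0, 2.757, 5.0, 3.0))
  st <- classify_concordance(tab, thr)
  expect_equal(as.character(st$class),
               c("lc_only", "low_low", "region_only", "both"))
  expect_equal(sum(st$counts), st$n)
  # ci_low operating point reclassifies the tie case as high/high
  st2 <- classify_concordance(tab, thr, threshold_point = "ci_low")
  expect_equal(as.character(st2$class)[2], "both")
})

test_that("classification is invariant to joint monotone rescaling", {
  sim <- gen_tangles(tangle_sim_spec(seed = 23L))
  thr <- derive_thresholds(sim$table, "hippocampus_tangle_density")
  st <- classify_concordance(sim$table, thr)
  tr <- function(v) log1p(2 * v)   # strictly monotone
  tab2 <- sim$table
  tab2$lc_tangle_density <- tr(tab2$lc_tangle_density)
  tab2$hippocampus_tangle_density <- tr(tab2$hippocampus_tangle_density)
  thr2 <- thr
  thr2$lc_cutoff_mean <- tr(thr$lc_cutoff_mean)
  thr2$region_cutoff_mean <- tr(thr$region_cutoff_mean)
  st2 <- classify_concordance(tab2, thr2)
  expect_identical(st$class, st2$class)
})

test_that("exact binomial machinery matches oracles and boundaries", {
  ci <- binomial_ci(32, 160)
  expect_equal(round(ci$ci_low, 2), 0.14)
  expect_equal(round(ci$ci_high, 2), 0.27)

  b0 <- binomial_ci(0, 10)
  expect_equal(b0$p_hat, 0); expect_equal(b0$ci_low, 0)
  bn <- binomial_ci(10, 10)
  expect_equal(bn$ci_high, 1)
  expect_error(binomial_ci(11, 10), "domain")

  oracle <- binom_ci_oracle(7, 25)
  ci7 <- binomial_ci(7, 25)
  expect_equal(c(ci7$ci_low, ci7$ci_high), oracle, tolerance = 1e-9)
})

test_that("exact intervals are conservative over random truths", {
  set.seed(11)
  n <- 160L
  covered <- 0L; trials <- 400L
  for (i in seq_len(trials)) {
    p <- runif(1, 0.02, 0.98)
    x <- rbinom(1, n, p)
    ci <- binomial_ci(x, n)
    if (ci$ci_low <= p && p <= ci$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / trials, 0.94)
})

test_that("Welch machinery matches the textbook formula and t.test", {
  a <- c(2.1, 2.5, 1.9, 2.7); b <- c(3.2, 3.9, 3.1, 3.6, 3.3)
  w <- welch_pairwise(rep(c("g1", "g2"), c(4, 5)), c(a, b))
  o <- welch_oracle(a, b)
  expect_equal(w$t, unname(o["t"]), tolerance = 1e-10)
  expect_equal(w$df, unname(o["df"]), tolerance = 1e-10)
  tt <- t.test(a, b)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_equal(c(w$ci_low, w$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-10)

  same <- welch_pairwise(rep(c("a", "b"), each = 6), rep(rnorm(6), 2))
  expect_equal(same$t, 0)
  expect_equal(same$ci_low, -same$ci_high)
})

test_that("Welch test is powered at the planted two-sd shift", {
  set.seed(12)
  hits <- 0L
  for (i in 1:50) {
    w <- welch_pairwise(rep(c("lo", "hi"), each = 50),
                        c(rnorm(50, 0, 1), rnorm(50, 2, 1)))
    if (w$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.99)
})

test_that("partial Spearman reduces, ranks and matches matrix algebra", {
  set.seed(13)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)

  z <- data.frame(junk = rnorm(40))
  mono <- partial_spearman(x, exp(3 * x), z)
  expect_equal(mono$rho, 1, tolerance = 1e-10)

  covs <- data.frame(a = rnorm(40), b = rnorm(40))
  ps2 <- partial_spearman(x, y, covs)
  expect_equal(ps2$rho, partial_spearman_oracle(x, y, covs),
               tolerance = 1e-12)
  expect_equal(ps2$df, 40L - 2L - 2L)

  expect_error(partial_spearman(rep(1, 40), y), "constant")
  expect_error(partial_spearman(x[1:4], y[1:4], covs[1:4, ]), "complete cases")
})

test_that("partial Spearman links LC to regional tangles in the generator", {
  sim <- gen_tangles(tangle_sim_spec(seed = 29L))
  tab <- sim$table
  for (gr in c("unimpaired", "impaired")) {
    sub <- tab[tab$group == gr, ]
    ps <- partial_spearman(sub$lc_tangle_density,
                           sub$hippocampus_tangle_density,
                           sub[, c("age", "sex", "lc_neuron_density", "pmi")])
    expect_gt(ps$rho, 0.3)
    expect_lt(ps$p, 0.001)
  }
})
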