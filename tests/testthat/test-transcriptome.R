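test_that("probe aggregation mean-averages per gene", {
  pm <- matrix(c(1, 3, 5,
                 3, 5, 7,
                 10, 10, 10), nrow = 3, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3"), c("s1", "s2", "s3")))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("gA", "gA", "gB"))
  out <- aggregate_probes(pm, map)
  expect_equal(out["gA", ], c(s1 = 2, s2 = 4, s3 = 6))
  expect_equal(out["gB", ], c(s1 = 10, s2 = 10, s3 = 10))

  # single-probe genes pass through unchanged
  expect_equal(unname(out["gB", ]), unname(pm["p3", ]))

  # naive-loop oracle on a random fixture
  set.seed(1)
  np <- 50
  genes <- sample(sprintf("g%02d", 1:18), np, replace = TRUE)
  m <- matrix(rnorm(np * 6), np,
              dimnames = list(sprintf("pr%02d", 1:np), NULL))
  map2 <- data.frame(probe_id = rownames(m), gene_id = genes)
  out2 <- aggregate_probes(m, map2)
  for (g in unique(genes)) {
    expect_equal(unname(out2[g, ]),
                 unname(colMeans(m[map2$gene_id == g, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  expect_error(aggregate_probes(m, map2[-1, ]), "missing from the probe map")
})

test_that("sample assignment follows the strict 3-mm rule", {
  arr <- array(0L, c(6, 6, 3))
  arr[2, 2, 2] <- 1L; arr[5, 5, 2] <- 2L
  atlas <- brain_volume(arr, affine = diag(c(2, 2, 2, 1)))
  # world coordinates of the labeled voxels (0-based indices times 2 mm)
  c1 <- c(2, 2, 2); c2 <- c(8, 8, 2)
  coords <- rbind(c1,                 # at a labeled center
                  c1 + c(2, 0, 0),    # 2 mm away -> assigned
                  c1 + c(3.5, 0, 0),  # 3.5 mm -> unassigned
                  c1 + c(3, 0, 0),    # exactly 3 mm -> strict, unassigned
                  c2 + c(0, 2, 0),
                  c(100, 100, 100))   # far outside the volume
  expect_equal(assign_samples(coords, atlas, 3),
               c(1L, 1L, NA, NA, 2L, NA))
  # equidistant tie resolves to the smaller label
  mid <- (c1 + c2) / 2
  arr2 <- arr; arr2[2, 2, 2] <- 2L; arr2[5, 5, 2] <- 1L
  atlas2 <- brain_volume(arr2, affine = diag(c(2, 2, 2, 1)))
  expect_equal(assign_samples(rbind(mid), atlas2, 100), 1L)
})

test_that("two-level medians aggregate donors then regions", {
  g <- c("g1", "g2")
  d1 <- matrix(c(1, 2, 9, 10, 20, 90), nrow = 2, byrow = TRUE,
               dimnames = list(g, NULL))
  l1 <- c(1L, 1L, 1L)
  out <- regional_medians(list(d1), list(l1), 1L)
  expect_equal(unname(out[, 1]), c(2, 20))   # median(1,2,9); median(10,20,90)

  # single donor, one sample per region: pass-through
  d2 <- matrix(c(5, 7, 50, 70), nrow = 2, byrow = TRUE,
               dimnames = list(g, NULL))
  out2 <- regional_medians(list(d2), list(c(1L, 2L)), 1:2)
  expect_equal(as.numeric(out2), c(5, 50, 7, 70))

  # 3-donor fixture against a nested-loop oracle
  set.seed(2)
  donors <- lapply(1:3, function(i)
    matrix(rnorm(4 * 6), 4, dimnames = list(sprintf("g%d", 1:4), NULL)))
  labels <- lapply(1:3, function(i) sample(1:2, 6, replace = TRUE))
  out3 <- regional_medians(donors, labels, 1:2)
  for (gi in 1:4) for (r in 1:2) {
    per_donor <- vapply(1:3, function(dn) {
      cols <- which(labels[[dn]] == r)
      if (length(cols) == 0) NA_real_
      else median(donors[[dn]][gi, cols])
    }, numeric(1))
    expect_equal(unname(out3[gi, as.character(r)]),
                 median(per_donor, na.rm = TRUE))
  }
  # region with no samples anywhere is flagged missing
  out4 <- regional_medians(donors, labels, 1:3)
  expect_true("3" %in% attr(out4, "missing_regions"))
})

test_that("similarity profile: identity, null bound and flags", {
  set.seed(3)
  ng <- 400
  expr <- cbind(LC = rnorm(ng), twin = NA, flat = 1,
                other = rnorm(ng))
  expr[, "twin"] <- expr[, "LC"]
  rownames(expr) <- sprintf("g%04d", 1:ng)
  prof <- similarity_profile(expr, "LC", n_perm = 199L, seed = 4L)
  twin <- prof[prof$region == "twin", ]
  expect_equal(twin$r, 1)
  expect_equal(twin$perm_p, 1 / 200)
  expect_true(is.na(prof$r[prof$region == "flat"]))
  expect_lt(abs(prof$r[prof$region == "other"]), 0.15)
  # determinism
  prof2 <- similarity_profile(expr, "LC", n_perm = 199L, seed = 4L)
  expect_identical(prof$perm_p, prof2$perm_p)
})

test_that("top-fraction sets are sized and tie-broken deterministically", {
  ng <- 100
  v <- seq(ng, 1)   # strictly decreasing by gene index
  expr <- cbind(A = v)
  rownames(expr) <- sprintf("g%03d", 1:ng)
  expect_equal(top_fraction_set(expr, "A", 0.05), sprintf("g%03d", 1:5))

  # tie straddling the boundary: ascending gene id wins
  v2 <- c(10, 9, 8, rep(7, 4), seq(6, length.out = ng - 7, by = -1))
  expr2 <- cbind(A = v2)
  rownames(expr2) <- sprintf("g%03d", 1:ng)
  expect_equal(top_fraction_set(expr2, "A", 0.05),
               c("g001", "g002", "g003", "g004", "g005"))
  expect_length(top_fraction_set(expr2, "A", 0.001), 0)
})

test_that("seed intersections and unions behave as set algebra", {
  set.seed(5)
  ng <- 200
  lc <- rnorm(ng)
  expr <- cbind(LC = lc, same = lc, indep = rnorm(ng), anti = -lc)
  rownames(expr) <- sprintf("g%03d", 1:ng)
  inter <- intersect_with_seed(expr, "LC", c("same", "anti"), 0.05)
  expect_setequal(inter$pairs$same, inter$seed_set)
  expect_length(inter$pairs$anti, 0)
  expect_equal(inter$union_size, length(unique(unlist(inter$pairs))))
  expect_true(all(unlist(inter$pairs) %in% inter$seed_set))
})

test_that("risk overlap p-values follow the hypergeometric tail", {
  genes <- sprintf("g%04d", 1:1000)
  risk <- genes[1:50]
  uni <- genes[26:125]   # overlap 25 of set size 100
  ov <- risk_overlap_probability(uni, risk, genes, n_draws = 4000L, seed = 6L)
  expect_equal(ov$observed_overlap, 25L)
  exact <- phyper(24, 50, 950, 100, lower.tail = FALSE)
  mc_sd <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(ov$p_one_tailed - exact), 3 * mc_sd + 5e-4)

  none <- risk_overlap_probability(genes[900:999], genes[1:50], genes,
                                   n_draws = 500L, seed = 7L)
  expect_equal(none$observed_overlap, 0L)
  expect_equal(none$p_one_tailed, 1, tolerance = 1 / 501 + 1e-12)

  all_of_them <- risk_overlap_probability(genes[1:50], genes[1:50], genes,
                                          n_draws = 500L, seed = 8L)
  expect_equal(all_of_them$p_one_tailed, 1 / 501)

  expect_warning(
    risk_overlap_probability(uni, c(risk, "nope"), genes, 200L, 9L),
    "outside the background")
})

test_that("generator-to-profile pipeline echoes the planted similarity", {
  sim <- gen_expression(expression_sim_spec(seed = 5L))
  mats <- lapply(sim$donor_probes, function(m)
    aggregate_probes(m, sim$probe_map))
  labels <- lapply(sim$donor_coords, function(co)
    assign_samples(co, sim$atlas, 3))
  expect_false(anyNA(unlist(labels)))
  expr <- regional_medians(mats, labels, seq_along(sim$region_names))
  colnames(expr) <- sim$region_names
  prof <- similarity_profile(expr, "LC", n_perm = 199L, seed = 10L)
  planted <- sim$truth$spec$correlated_regions$region
  expect_setequal(utils::head(prof$region, 5), planted)
  hip <- prof[prof$region == "hippocampus", ]
  expect_lt(abs(hip$r - 0.31), 0.05)
  expect_lt(hip$perm_p, 0.05)

  inter <- intersect_with_seed(expr, "LC", utils::head(prof$region, 5), 0.05)
  ov <- risk_overlap_probability(inter$union, sim$risk_genes,
                                 rownames(expr), 1000L, seed = 11L)
  expect_equal(ov$observed_overlap, 3L)
})
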