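test_that("select_edges finds perfectly coupled edges with the right sign", {
  withr::local_seed(2)
  x <- matrix(rnorm(30 * 50), 30, 50)
  y <- x[, 7]                       # behavior equals one edge
  sel <- select_edges(x, y)
  expect_true(7 %in% sel$positive)
  expect_equal(sel$r[7], 1, tolerance = 1e-12)
  # sign symmetry: negated behavior puts the edge in the negative set
  sel2 <- select_edges(x, -y)
  expect_true(7 %in% sel2$negative)
  expect_equal(sel2$r, -sel$r, tolerance = 1e-12)
})

test_that("select_edges p-values match cor.test and flag constant columns", {
  withr::local_seed(3)
  x <- matrix(rnorm(25 * 10), 25, 10)
  x[, 4] <- 1
  y <- rnorm(25)
  expect_warning(sel <- select_edges(x, y), "constant")
  expect_true(is.na(sel$r[4]))
  for (k in c(1, 9)) {
    ct <- cor.test(x[, k], y)
    expect_equal(sel$r[k], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sel$p[k], ct$p.value, tolerance = 1e-10)
  }
  expect_error(select_edges(x, rep(2, 25)), "zero variance")
})

test_that("network strength sums edges and is additive over disjoint sets", {
  v <- c(0.7, -0.2, 0.1, 0.4, 0, 0.3)
  expect_identical(network_strength(v, integer(0)), 0)
  expect_identical(network_strength(v, 1L), 0.7)
  a <- c(1L, 3L); b <- c(2L, 6L)
  expect_equal(network_strength(v, c(a, b)),
               network_strength(v, a) + network_strength(v, b))
  m <- rbind(v, v * 2)
  expect_equal(network_strength(m, a), c(0.8, 1.6))
})

test_that("noiseless planted network is recovered with near-perfect CV", {
  co <- make_cpm_cohort(noise = 0, seed = 4)
  model <- cross_validate(co$x, co$y, cpm_config())
  expect_true(all(co$planted %in% model$consensus_positive))
  expect_gte(model$performance$r["positive"], 0.95)
  expect_gte(model$performance$r["combined"], 0.95)
  # consensus is the intersection: contained in every fold's selection
  for (f in seq_along(model$fold_positive)) {
    expect_true(all(model$consensus_positive %in% model$fold_positive[[f]]))
  }
})

test_that("LOOCV fast path equals explicit training-set selection", {
  co <- make_cpm_cohort(n = 20, n_regions = 10, planted = 1:5, noise = 2,
                        seed = 5)
  model <- cross_validate(co$x, co$y, cpm_config())
  for (f in c(1, 11, 20)) {
    sel <- select_edges(co$x[-f, ], co$y[-f], alpha = 0.005, warn = FALSE)
    expect_identical(model$fold_positive[[f]], sel$positive)
    expect_identical(model$fold_negative[[f]], sel$negative)
  }
})

test_that("held-out subjects cannot leak into fold selections", {
  co <- make_cpm_cohort(n = 25, n_regions = 10, planted = 1:5, noise = 2,
                        seed = 6)
  model <- cross_validate(co$x, co$y, cpm_config())
  # corrupt subject 9's edge values wildly; fold 9 (which excludes subject
  # 9) must select identically
  x2 <- co$x
  x2[9, ] <- x2[9, ] + 100 * co$y[9]
  model2 <- cross_validate(x2, co$y, cpm_config())
  expect_identical(model2$fold_positive[[9]], model$fold_positive[[9]])
  expect_identical(model2$fold_negative[[9]], model$fold_negative[[9]])
})

test_that("consensus is invariant to subject ordering under LOOCV", {
  co <- make_cpm_cohort(n = 18, n_regions = 10, planted = 1:4, noise = 1,
                        seed = 7)
  perm <- withr::with_seed(8, sample(18))
  m1 <- cross_validate(co$x, co$y, cpm_config())
  m2 <- cross_validate(co$x[perm, ], co$y[perm], cpm_config())
  expect_identical(sort(m1$consensus_positive), sort(m2$consensus_positive))
})

test_that("empty selections fall back to the training mean with a warning", {
  withr::local_seed(9)
  x <- matrix(rnorm(15 * 20), 15, 20)
  y <- rnorm(15)                    # behavior unrelated to any edge
  expect_warning(model <- cross_validate(x, y, cpm_config(select_alpha = 1e-6)),
                 "no edges")
  expect_true(all(is.finite(model$predictions)))
  expect_identical(model$performance$r[["positive"]], 0)
})

test_that("k-fold assignment is stratified, seeded, and reproducible", {
  groups <- rep(c("patient", "control"), c(10, 14))
  cfg <- cpm_config(cv = "kfold", k = 4, seed = 3)
  f1 <- connectopipe:::make_folds(24, cfg, groups)
  f2 <- connectopipe:::make_folds(24, cfg, groups)
  expect_identical(f1, f2)
  expect_identical(sort(unlist(f1)), 1:24)
  # stratification: each fold carries members of both groups
  for (f in f1) expect_true(any(f <= 10) && any(f > 10))

  co <- make_cpm_cohort(n = 24, n_regions = 12, planted = 1:6, noise = 0.5,
                        seed = 10)
  mk <- cross_validate(co$x, co$y, cfg, groups = groups)
  expect_length(mk$folds, 4)
  expect_true(all(is.finite(mk$predictions)))
})

test_that("permutation p hits its lower bound for a strong signal", {
  co <- make_cpm_cohort(n = 30, n_regions = 10, planted = 1:6, noise = 0.2,
                        seed = 11)
  pt <- permutation_test(co$x, co$y, cpm_config(n_permutations = 99, seed = 5))
  expect_equal(unname(pt$p["positive"]), 1 / 100, tolerance = 1e-12)
  # permuted behavior: p should be far from significant
  yperm <- withr::with_seed(6, sample(co$y))
  pt0 <- permutation_test(co$x, yperm, cpm_config(n_permutations = 99, seed = 5))
  expect_gt(pt0$p["positive"], 0.05)
})

test_that("degree tables satisfy the handshake identity", {
  # edges {(1,2),(1,3)}: node 1 has degree 2, others 1
  deg <- degree_table(c(1L, 2L), n_regions = 5)
  expect_identical(deg$degree[deg$region == 1], 2L)
  expect_identical(deg$degree[deg$region == 2], 1L)
  expect_identical(deg$degree[deg$region == 3], 1L)

  withr::local_seed(12)
  for (r in 1:100) {
    n_reg <- sample(5:20, 1)
    edges <- sample.int(n_edges(n_reg), sample(1:10, 1))
    expect_identical(sum(degree_table(edges, n_reg)$degree),
                     2L * length(edges))
  }
  # star on k edges: hub degree k
  star <- connectopipe:::pair_to_edge(rep(1L, 4), 2:5, 10)
  expect_identical(degree_table(star, 10)$degree[1], 4L)
})

test_that("high-degree follow-up recovers a planted hub", {
  withr::local_seed(13)
  n <- 40; n_reg <- 12
  star <- connectopipe:::pair_to_edge(rep(1L, 8), 2:9, n_reg)
  x <- matrix(rnorm(n * n_edges(n_reg), 0.3, 0.2), n, n_edges(n_reg))
  g <- rnorm(n, 0, 0.25)            # coherent hub: shared strength factor
  x[, star] <- 0.3 + g + matrix(rnorm(n * 8, 0, 0.05), n, 8)
  y <- rowSums(x[, star]) + rnorm(n, 0, 0.3)
  model <- cross_validate(x, y, cpm_config())
  tab <- high_degree_followup(x, y, model, n_regions = n_reg, k = 3)
  expect_identical(tab$region[1], 1L)        # the hub dominates
  full_r <- model$performance$r["positive"]
  expect_gt(tab$r[1], full_r - 0.1)          # hub subnetwork ~ full model
  expect_true(all(tab$p_fdr >= tab$p - 1e-15))
})

test_that("partial correlation residualizes covariates", {
  withr::local_seed(14)
  n <- 80
  c1 <- rnorm(n)
  a <- 2 * c1 + rnorm(n)
  b <- -3 * c1 + rnorm(n)
  plain <- partial_cor(a, b)
  adj <- partial_cor(a, b, covariates = cbind(c1))
  expect_lt(plain$r, -0.5)            # spurious via the shared covariate
  expect_lt(abs(adj$r), 0.25)         # vanishes after adjustment
  expect_equal(adj$df, n - 3)
  # with no covariates it matches cor.test
  ct <- cor.test(a, b)
  expect_equal(plain$p, ct$p.value, tolerance = 1e-10)
})

test_that("groupwise evaluation isolates group-specific coupling", {
  withr::local_seed(15)
  n1 <- 30; n2 <- 30
  s <- rnorm(n1 + n2)
  y <- c(2 * s[1:n1] + rnorm(n1, 0, 0.5), rnorm(n2))  # only group 1 coupled
  groups <- rep(c("patient", "control"), c(n1, n2))
  gw <- groupwise_evaluation(s, y, groups)
  expect_lt(gw$p[gw$group == "patient"], 0.001)
  expect_gt(gw$p[gw$group == "control"], 0.05)
  expect_warning(groupwise_evaluation(s[1:33], y[1:33],
                                      rep(c("a", "b"), c(30, 3))),
                 "fewer than 4")
})
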