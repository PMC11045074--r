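test_that("simulated LOD distributions are seed-deterministic", {
  m <- kin_model(c(locus_model(1:3, c(0.5, 0.3, 0.2), "A"),
                   locus_model(1:2, c(0.7, 0.3), "B")))
  s1 <- simulate(m, nsim = 500, seed = 3, category = "PO")
  s2 <- simulate(m, nsim = 500, seed = 3, category = "PO")
  expect_identical(s1, s2)
  s3 <- simulate(m, nsim = 500, seed = 4, category = "PO")
  expect_false(identical(s1$lod_PO, s3$lod_PO))
})

test_that("PO simulation reproduces the exact genotype-pair probabilities", {
  # asymmetric biallelic locus so each genotype pair has a distinct LOD:
  # P(AA, AA | PO) = p^3 = 0.343 at p = 0.7 (hand computation, and the only
  # pair whose LOD_PO equals ln(T(AA|AA)/P_HWE(AA)) = -ln(0.7))
  m <- kin_model(locus_model(1:2, c(0.7, 0.3)), epsilon = 0)
  sim <- simulate(m, nsim = 1e5, seed = 5, category = "PO")
  target <- -log(0.7)
  frac <- mean(abs(sim$lod_PO - target) < 1e-12)
  p_true <- 0.7^3
  se <- sqrt(p_true * (1 - p_true) / 1e5)
  expect_lt(abs(frac - p_true), 3 * se)
})

test_that("SELF pairs at zero error always have identical genotypes", {
  m <- kin_model(locus_model(1:2, c(0.5, 0.5)), epsilon = 0)
  sim <- simulate(m, nsim = 2000, seed = 6, category = "SELF",
                  include_self = TRUE)
  # self-LOD of an identical pair is -log P_HWE(g): only two values possible
  allowed <- c(-log(0.25), -log(0.5))
  expect_true(all(vapply(sim$lod_SELF,
                         function(x) any(abs(x - allowed) < 1e-12),
                         logical(1))))
})

test_that("mean exp(LOD_PO) over simulated unrelated pairs is 1 within MC error", {
  # moderately informative panel so the empirical SE is trustworthy
  loci <- do.call(c, lapply(1:6, function(i)
    locus_model(1:2, c(0.5, 0.5), paste0("L", i))))
  m <- kin_model(loci, epsilon = 0.0077)
  sim <- simulate(m, nsim = 5e4, seed = 7, category = "U")
  w <- exp(sim$lod_PO)
  se <- stats::sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 1), 3 * se)
})

test_that("LOD_PO distributions are stochastically ordered PO > HS > U", {
  sim <- study_fixture(seed = 10)
  m <- kin_model(deduplicate(sim$samples, seed = 110)$samples)
  su <- simulate(m, nsim = 2e4, seed = 11, category = "U")
  sh <- simulate(m, nsim = 2e4, seed = 12, category = "HS")
  sp <- simulate(m, nsim = 2e4, seed = 13, category = "PO")
  grid <- stats::quantile(c(su$lod_PO, sh$lod_PO, sp$lod_PO),
                          probs = seq(0.05, 0.95, 0.05))
  Fu <- stats::ecdf(su$lod_PO)(grid)
  Fh <- stats::ecdf(sh$lod_PO)(grid)
  Fp <- stats::ecdf(sp$lod_PO)(grid)
  expect_true(all(Fp <= Fh + 0.01))
  expect_true(all(Fh <= Fu + 0.01))
})

test_that("the unrelated LOD_PO distribution is multimodal by incompatible-locus count", {
  # six equifrequent biallelic loci; true genotype pairs drawn under U in
  # test code, scored with and without error to count PO-incompatible loci
  loci <- do.call(c, lapply(1:6, function(i)
    locus_model(1:2, c(0.5, 0.5), paste0("L", i))))
  m <- kin_model(loci, epsilon = 0.0077)
  m0l <- lapply(1:6, function(l) kin_model(loci[l], epsilon = 0))
  set.seed(21)
  n <- 3000
  draw <- function() matrix(sample(1:2, 2 * 6 * n, replace = TRUE), n)
  g1 <- draw(); g2 <- draw()
  lod_eps <- numeric(n); n_incomp <- integer(n)
  for (r in seq_len(n)) {
    lod_eps[r] <- pair_lod(m, g1[r, ], g2[r, ], "PO")
    per <- vapply(1:6, function(l)
      pair_lod(m0l[[l]], g1[r, c(2 * l - 1, 2 * l)],
               g2[r, c(2 * l - 1, 2 * l)], "PO"), numeric(1))
    n_incomp[r] <- sum(is.infinite(per))
  }
  means <- tapply(lod_eps, n_incomp, mean)
  expect_gte(length(means), 3)           # several modes occupied
  expect_true(all(diff(means) < 0))      # strictly decreasing mode centres
  # modes are separated: incompatibility costs ~log(eps) per locus
  expect_true(all(diff(means) < -3))
})

test_that("error rates are monotone in the cut-off with correct limits", {
  sim <- study_fixture(seed = 14)
  m <- kin_model(deduplicate(sim$samples, seed = 114)$samples)
  su <- simulate(m, nsim = 1e4, seed = 15, category = "U")
  sp <- simulate(m, nsim = 1e4, seed = 16, category = "PO")
  r <- error_rates(su, sp, cutoffs = c(-Inf, 3:8, Inf))
  po <- r[r$scored == "PO" & r$category == "PO", ]
  po <- po[order(po$cutoff), ]
  expect_true(all(diff(po$fp_rate) <= 0))
  expect_true(all(diff(po$fn_rate) >= 0))
  expect_equal(po$fp_rate[po$cutoff == Inf], 0)
  expect_equal(po$fn_rate[po$cutoff == Inf], 1)
  # at cutoff -Inf the FN rate is pure ML misclassification
  expect_equal(po$fn_rate[po$cutoff == -Inf],
               mean(sp$ml_category != "PO"))
  expect_error(error_rates(su, sp, cutoffs = numeric(0)), "empty")
})

test_that("fully separated distributions give zero error between supports", {
  su <- sp <- simulate(kin_model(locus_model(1:2, c(0.5, 0.5))),
                       nsim = 10, seed = 1, category = "U")
  su$lod_PO <- seq(-10, -5, length.out = 10); su$ml_category <- "U"
  sp$lod_PO <- seq(5, 10, length.out = 10); sp$ml_category <- "PO"
  r <- error_rates(su, sp, cutoffs = 0, scored = "PO")
  po <- r[r$category == "PO", ]
  expect_equal(po$fp_rate, 0)
  expect_equal(po$fn_rate, 0)
})

test_that("cut-off table counts decrease with the cut-off and scale with n_pairs", {
  sim <- study_fixture(seed = 17)
  dd <- deduplicate(sim$samples, seed = 117)
  m <- kin_model(dd$samples)
  pr <- predict(m, dd$samples)
  su <- simulate(m, nsim = 1e4, seed = 18, category = "U")
  sp <- simulate(m, nsim = 1e4, seed = 19, category = "PO")
  rates <- error_rates(su, sp, cutoffs = 3:8)
  ct <- build_cutoff_table(pr, rates)
  for (cat in c("FS", "HS", "PO")) {
    obs <- ct$observed[ct$scored == "PO" & ct$category == cat]
    expect_true(all(diff(obs[order(3:8)]) <= 0))
  }
  ct0 <- build_cutoff_table(pr, rates, n_pairs_total = 0)
  expect_true(all(ct0$expected_fp == 0))
})

test_that("corrected kin count arithmetic and fixed point behave", {
  expect_equal(corrected_kin_count(25, 4, expected_fn = 8), 29)
  expect_equal(corrected_kin_count(10, 0, expected_fn = 0), 10)
  # fixed point agrees with the closed form (obs - fp) / (1 - fn_rate)
  for (fn in c(0, 0.1, 0.3, 0.7))
    expect_equal(corrected_kin_count(25, 4, fn_rate = fn),
                 (25 - 4) / (1 - fn), tolerance = 1e-5)
  expect_warning(corrected_kin_count(1, 5, expected_fn = 0), "negative")
})
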