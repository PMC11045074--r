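make_sp <- function(delta_lon, same_day_pos, lod_hs,
                    ml_category = "U", lod_po = lod_hs) {
  out <- data.frame(id_i = "a", id_j = "b", delta_lon = delta_lon,
                    same_day_pos = same_day_pos, lod_hs = lod_hs,
                    lod_po = lod_po, ml_category = ml_category,
                    stringsAsFactors = FALSE)
  class(out) <- c("spatial_pairs", "data.frame")
  out
}

test_that("longitude differences use the minimal angular convention", {
  expect_equal(delta_longitude(95.94, 108.86), 12.92)
  expect_equal(delta_longitude(-170, 170), 20)   # antimeridian
  expect_equal(delta_longitude(0, 180), 180)
  set.seed(31)
  l1 <- runif(500, -180, 180); l2 <- runif(500, -180, 180)
  d <- delta_longitude(l1, l2)
  expect_true(all(d >= 0 & d <= 180))
  expect_equal(d, delta_longitude(l2, l1))
})

test_that("spatial pairs carry same-day/vessel flags, sector and MC filters", {
  sim <- study_fixture(seed = 32)
  dd <- deduplicate(sim$samples, seed = 132)
  m <- kin_model(dd$samples)
  pr <- predict(m, dd$samples)
  sp <- make_spatial_pairs(pr, dd$samples, exclude_field_mc = FALSE)
  meta <- dd$samples$meta
  # field MC pairs were sampled at the same encounter: flag must be TRUE
  mc_rows <- sp$same_day_pos[
    mapply(function(i, j) {
      fi <- meta$field_obs[match(i, meta$sample_id)]
      !is.na(fi) && fi == paste0("MC:", j)
    }, sp$id_i, sp$id_j)]
  expect_true(all(mc_rows))
  # excluding field MC pairs drops exactly those pairs
  sp2 <- make_spatial_pairs(pr, dd$samples, exclude_field_mc = TRUE)
  expect_equal(nrow(sp) - nrow(sp2), sum(!is.na(meta$field_obs)) / 2)
  # sector filter keeps only pairs fully inside
  sp3 <- make_spatial_pairs(pr, dd$samples, sector = c(100, 120))
  lon_i <- meta$lon[match(sp3$id_i, meta$sample_id)]
  lon_j <- meta$lon[match(sp3$id_j, meta$sample_id)]
  expect_true(all(lon_i >= 100 & lon_i <= 120 & lon_j >= 100 & lon_j <= 120))
})

test_that("rank-sum test: exact small-sample p-value and identical-group null", {
  sp <- make_sp(delta_lon = c(1, 2, 3, 4), same_day_pos = FALSE,
                lod_hs = 0, ml_category = c("PO", "PO", "U", "U"))
  r <- wilcoxon_delta_lon(sp)
  expect_equal(r$p_value, 1 / 3)   # enumeration over C(4,2) assignments
  expect_equal(r$n_a, 2); expect_equal(r$n_b, 2)

  # identical distributions: p of 1 under the tie-corrected approximation
  sp2 <- make_sp(delta_lon = rep(1:10, 2), same_day_pos = FALSE, lod_hs = 0,
                 ml_category = rep(c("PO", "U"), each = 10))
  expect_gt(wilcoxon_delta_lon(sp2)$p_value, 0.99)

  # empty group: defined not-testable result
  sp3 <- make_sp(delta_lon = 1:4, same_day_pos = FALSE, lod_hs = 0,
                 ml_category = "U")
  expect_false(wilcoxon_delta_lon(sp3)$testable)
})

test_that("rank-sum test detects a planted longitudinal shift in kin pairs", {
  n_rep <- 100
  rej <- 0
  for (s in seq_len(n_rep)) {
    set.seed(4000 + s)
    n_po <- 25; n_u <- 400
    dl_u <- runif(n_u, 0, 50)
    dl_po <- pmax(runif(n_po, 0, 50) - 20, 0)   # kin aggregate westward
    sp <- make_sp(delta_lon = c(dl_po, dl_u), same_day_pos = FALSE,
                  lod_hs = 0, ml_category = rep(c("PO", "U"), c(n_po, n_u)))
    rej <- rej + (wilcoxon_delta_lon(sp)$p_value < 0.05)
  }
  expect_gt(rej / n_rep, 0.8)
})

test_that("rank-sum type-I error is near nominal under the null", {
  n_rep <- 300
  p <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    set.seed(5000 + s)
    sp <- make_sp(delta_lon = runif(120, 0, 50), same_day_pos = FALSE,
                  lod_hs = 0,
                  ml_category = rep(c("PO", "U"), c(20, 100)))
    p[s] <- wilcoxon_delta_lon(sp)$p_value
  }
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("intercept-only quantile fits equal empirical quantiles exactly", {
  set.seed(33)
  y <- rnorm(157)
  sp <- make_sp(delta_lon = 0, same_day_pos = FALSE, lod_hs = y)
  suppressWarnings(q <- quantile_regression(sp, taus = c(0.5, 0.9, 0.95, 0.975),
                                            n_boot = 5, seed = 1))
  b0 <- q$estimate[q$term == "b0"]
  expect_equal(b0, unname(quantile(y, c(0.5, 0.9, 0.95, 0.975), type = 1)),
               tolerance = 1e-8)
})

test_that("a noiseless linear response is recovered at every quantile", {
  set.seed(34)
  n <- 80
  sdp <- rep(c(TRUE, FALSE), n / 2)
  dlon <- runif(n, 0, 40)
  y <- 2 + 1.5 * sdp - 0.1 * dlon
  sp <- make_sp(delta_lon = dlon, same_day_pos = sdp, lod_hs = y)
  q <- quantile_regression(sp, taus = c(0.9, 0.95), n_boot = 5, seed = 1)
  expect_equal(q$estimate[q$term == "b0"], c(2, 2), tolerance = 1e-6)
  expect_equal(q$estimate[q$term == "b1_same_day_pos"], c(1.5, 1.5),
               tolerance = 1e-6)
  expect_equal(q$estimate[q$term == "b2_delta_lon"], c(-0.1, -0.1),
               tolerance = 1e-6)
})

test_that("quantile fits satisfy the residual sign-balance condition", {
  set.seed(35)
  n <- 200
  sdp <- runif(n) < 0.3
  dlon <- runif(n, 0, 50)
  y <- rnorm(n) + 0.5 * sdp + 0.01 * dlon
  sp <- make_sp(delta_lon = dlon, same_day_pos = sdp, lod_hs = y)
  q <- quantile_regression(sp, taus = c(0.5, 0.9, 0.95), n_boot = 5, seed = 1)
  X <- cbind(1, as.numeric(sdp), dlon)
  for (tau in c(0.5, 0.9, 0.95)) {
    b <- q$estimate[q$tau == tau]
    r <- y - drop(X %*% b)
    expect_lte(mean(r < 0), tau + 1e-9)
    expect_gte(mean(r <= 0), tau - 1e-9)
  }
})

test_that("bootstrap confidence bands are seed-reproducible", {
  set.seed(36)
  sp <- make_sp(delta_lon = runif(80, 0, 50), same_day_pos = runif(80) < 0.3,
                lod_hs = rnorm(80))
  q1 <- quantile_regression(sp, taus = 0.9, n_boot = 50, seed = 7)
  q2 <- quantile_regression(sp, taus = 0.9, n_boot = 50, seed = 7)
  expect_identical(q1, q2)
})

test_that("degenerate designs fall back to an intercept-only fit with warning", {
  sp <- make_sp(delta_lon = 5, same_day_pos = FALSE, lod_hs = rnorm(30))
  expect_warning(q <- quantile_regression(sp, taus = 0.9, n_boot = 5, seed = 1),
                 "degenerate")
  expect_equal(unique(q$term), "b0")
})

test_that("ECDF comparison reflects translation and stratum identity", {
  set.seed(37)
  y <- rnorm(200)
  sp <- make_sp(delta_lon = 0, same_day_pos = rep(c(TRUE, FALSE), 100),
                lod_hs = c(rbind(y[1:100], y[1:100])))
  ec <- ecdf_compare(sp, ref_lod = 1.8)
  grid <- seq(-3, 3, 0.1)
  expect_equal(ec$ecdf_same_day(grid), ec$ecdf_other(grid))
  expect_equal(ec$ref_lod, 1.8)

  # shifting a stratum by c translates its ECDF exactly
  sp2 <- sp; sp2$lod_hs[sp2$same_day_pos] <- sp2$lod_hs[sp2$same_day_pos] + 2
  ec2 <- ecdf_compare(sp2)
  expect_equal(ec2$ecdf_same_day(grid + 2), ec2$ecdf_other(grid))

  sp3 <- make_sp(delta_lon = 0, same_day_pos = FALSE, lod_hs = rnorm(10))
  expect_warning(ec3 <- ecdf_compare(sp3), "empty")
  expect_null(ec3$ecdf_same_day)
})
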