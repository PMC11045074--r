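make_dyad_df <- function(...) {
  base <- data.frame(id_i = "A", id_j = "B", lod_PO = 10, lod_HS = 7,
                     lod_FS = 8, sex_i = "F", sex_j = "M", hap_i = "H1",
                     hap_j = "H1", length_i = NA_real_, length_j = NA_real_,
                     stringsAsFactors = FALSE)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("dyad selection keeps pairs above the cut-off, sorted by LOD", {
  sim <- study_fixture(seed = 22)
  dd <- deduplicate(sim$samples, seed = 122)
  m <- kin_model(dd$samples)
  pr <- predict(m, dd$samples)
  dy <- select_dyads(pr, dd$samples, cutoff = 6)
  expect_true(all(dy$lod_PO > 6))
  expect_true(all(diff(dy$lod_PO) <= 0))
  expect_true(all(dy$cutoff_passed == 6))
  # cut-off above the maximum gives an empty list
  dy_hi <- select_dyads(pr, dd$samples, cutoff = max(pr$lod_PO) + 1)
  expect_equal(nrow(dy_hi), 0)
  # a strong pair with LOD_PO 12.55 / LOD_HS 8.83 passes and is ML PO
  pr2 <- pr[1, , drop = FALSE]
  pr2$lod_PO <- 12.55; pr2$lod_HS <- 8.83; pr2$lod_FS <- 10.0
  pr2$ml_category <- "PO"
  dy2 <- select_dyads(pr2, dd$samples, cutoff = 6)
  expect_equal(nrow(dy2), 1)
  expect_equal(dy2$ml_category, "PO")
})

test_that("maternal annotation follows the mtDNA/sex rules exhaustively", {
  sexes <- c("F", "M", NA)
  haps <- c("H1", "H2", NA)
  for (s1 in sexes) for (s2 in sexes) for (h1 in haps) for (h2 in haps) {
    d <- annotate_maternal(make_dyad_df(sex_i = s1, sex_j = s2,
                                        hap_i = h1, hap_j = h2))
    lab <- d$maternal
    if (is.na(h1) || is.na(h2) || is.na(s1) || is.na(s2)) {
      expect_equal(lab, "n/a")
    } else if (h1 != h2) {
      expect_equal(lab, "none")   # never MS/MD on differing haplotypes
    } else if (setequal(c(s1, s2), c("M", "F"))) {
      expect_equal(lab, "MS")
    } else if (s1 == "F" && s2 == "F") {
      expect_equal(lab, "MD")
    } else {
      expect_equal(lab, "none")   # male-male cannot be maternal
    }
  }
})

test_that("the presumed mother is the larger individual where lengths allow", {
  d <- annotate_maternal(make_dyad_df(sex_i = "F", sex_j = "F",
                                      length_i = 13.6, length_j = 10.0))
  expect_equal(d$maternal, "MD")
  expect_equal(d$presumed_mother, "A")
  # MS where the female is larger: mother identified
  d2 <- annotate_maternal(make_dyad_df(sex_i = "F", sex_j = "M",
                                       length_i = 15.4, length_j = 14.1))
  expect_equal(d2$maternal, "MS")
  expect_equal(d2$presumed_mother, "A")
  # MS where the male is larger: no mother flagged
  d3 <- annotate_maternal(make_dyad_df(sex_i = "F", sex_j = "M",
                                       length_i = 12.0, length_j = 14.0))
  expect_equal(d3$maternal, "MS")
  expect_true(is.na(d3$presumed_mother))
  # lengths unknown: label but no flag
  d4 <- annotate_maternal(make_dyad_df(sex_i = "F", sex_j = "F"))
  expect_true(is.na(d4$presumed_mother))
})

test_that("triads are connected components of three or more dyad members", {
  dy <- data.frame(id_i = c("A", "A"), id_j = c("B", "C"),
                   lod_PO = c(9, 8), lod_HS = c(5, 4),
                   ml_category = "PO", stringsAsFactors = FALSE)
  tr <- build_triads(dy)
  expect_length(tr, 1)
  expect_setequal(tr[[1]]$members, c("A", "B", "C"))
  expect_equal(tr[[1]]$shared, "A")

  dy2 <- data.frame(id_i = c("A", "C"), id_j = c("B", "D"),
                    lod_PO = 9, lod_HS = 5, ml_category = "PO")
  expect_length(build_triads(dy2), 0)

  dy3 <- data.frame(id_i = c("A", "B", "C"), id_j = c("B", "C", "A"),
                    lod_PO = 9, lod_HS = 5, ml_category = "PO")
  tr3 <- build_triads(dy3)
  expect_length(tr3, 1)
  expect_setequal(tr3[[1]]$shared, c("A", "B", "C"))

  # partition refinement: no individual in two components
  sim <- study_fixture(seed = 23)
  dd <- deduplicate(sim$samples, seed = 123)
  dy4 <- select_dyads(predict(kin_model(dd$samples), dd$samples),
                      dd$samples, cutoff = 6)
  tr4 <- build_triads(dy4)
  all_members <- unlist(lapply(tr4, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("elapsed time floors to whole years and handles same-day pairs", {
  dy <- make_dyad_df(date_i = as.Date("1998-02-10"),
                     date_j = as.Date("2015-02-24"))
  et <- elapsed_time_summary(dy)
  expect_equal(et$elapsed_years, 17)
  expect_equal(et$first_date, as.Date("1998-02-10"))

  dy2 <- make_dyad_df(date_i = as.Date("2015-02-25"),
                      date_j = as.Date("2015-02-25"))
  expect_equal(elapsed_time_summary(dy2)$elapsed_years, 0)

  dy3 <- rbind(dy, make_dyad_df(date_i = as.Date(NA),
                                date_j = as.Date("2010-01-01")))
  expect_warning(et3 <- elapsed_time_summary(dy3), "missing sampling date")
  expect_equal(nrow(et3), 1)
  expect_equal(attr(et3, "max_years"), 17)
})

test_that("compatibly genotyped field mother-calf pairs are recovered at the cut-off", {
  for (seed in c(24, 25)) {
    sim <- study_fixture(seed = seed)
    dd <- deduplicate(sim$samples, seed = seed + 100)
    m <- kin_model(dd$samples)
    m0 <- kin_model(estimate_allele_freqs(dd$samples), epsilon = 0)
    dy <- select_dyads(predict(m, dd$samples), dd$samples, cutoff = 6)
    meta <- dd$samples$meta
    mc <- meta$sample_id[!is.na(meta$field_obs)]
    mc_pairs <- unique(t(apply(cbind(
      mc, sub("^MC:", "", meta$field_obs[match(mc, meta$sample_id)])),
      1, sort)))
    # keep pairs whose observed genotypes are Mendelian-compatible at every
    # locus (a genotyping error can make a true pair incompatible, which is
    # exactly what the error model's finite LOD penalty is for)
    compatible <- apply(mc_pairs, 1, function(pr) {
      i <- match(pr[1], meta$sample_id); j <- match(pr[2], meta$sample_id)
      is.finite(pair_lod(m0, dd$samples$geno[i, ], dd$samples$geno[j, ], "PO"))
    })
    expect_gt(sum(compatible), 0)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    kk <- key(mc_pairs[compatible, 1], mc_pairs[compatible, 2])
    pr <- predict(m, dd$samples)
    prk <- key(pr$id_i, pr$id_j)
    # every compatibly genotyped mother-calf pair is classified as first-
    # degree kin by maximum likelihood ...
    expect_true(all(pr$ml_category[match(kk, prk)] %in% c("PO", "FS")))
    # ... most clear the working cut-off (a minority of true pairs falling
    # below it is expected at this marker informativeness), and every one
    # that does is in the dyad list with its field confirmation attached
    dyk <- key(dy$id_i, dy$id_j)
    above <- kk[pr$lod_PO[match(kk, prk)] > 6]
    expect_gte(length(above), length(kk) / 2)
    expect_true(all(above %in% dyk))
    expect_true(all(dy$field_confirmed[match(above, dyk)]))
  }
})
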