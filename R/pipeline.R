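#' Run the full close-kin analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a sample table: duplicate
#' detection (provisional frequency model), re-estimation of allele
#' frequencies on unique individuals, Hardy-Weinberg QC, pairwise LOD
#' scoring, Monte-Carlo cut-off calibration with false-positive/negative
#' accounting, dyad selection and maternal annotation at the chosen
#' cut-off, triad assembly, elapsed-time summaries, and the two
#' geography-kinship analyses (rank-sum test on longitude differences and
#' tail quantile regression with the sampling-proximity covariate). All
#' randomness is controlled by \code{seed}; per-stage streams are derived
#' from it, so a rerun with the same inputs is identical. When
#' \code{out_dir} is given, every table is written as CSV together with a
#' machine-readable JSON summary and the resolved configuration.
#'
#' @param samples a [kin_samples] object (raw records; deduplication is the
#'   first stage).
#' @param out_dir optional output directory (created if needed).
#' @param epsilon,error_mode genotyping error model (see [kin_model()]).
#' @param cutoffs LOD cut-off grid for the calibration table.
#' @param cutoff the working cut-off for dyad selection.
#' @param n_sim simulated genotype pairs per kinship category.
#' @param seed master RNG seed.
#' @param sector_wilcoxon longitude sector for the restricted rank-sum run.
#' @param sector_qr longitude sector for the quantile regression.
#' @param taus quantile levels for the tail regression.
#' @param n_boot bootstrap resamples for the regression bands.
#' @param exclude_field_mc drop field-observed mother-calf pairs from the
#'   spatial analyses.
#' @return A list of class \code{kin_pipeline} with elements \code{dedup},
#'   \code{freqs}, \code{hwe}, \code{model}, \code{pairs},
#'   \code{cutoff_table}, \code{dyads}, \code{triads}, \code{elapsed},
#'   \code{wilcoxon} (full and sector-restricted), \code{qr},
#'   \code{ecdf}, \code{summary} (stage counts), \code{config}.
#' @export
run_kin_pipeline <- function(samples, out_dir = NULL, epsilon = 0.0077,
                             error_mode = "freq_draw", cutoffs = 3:8,
                             cutoff = 6, n_sim = 1e5, seed = 1,
                             sector_wilcoxon = c(85, 135),
                             sector_qr = c(80, 135),
                             taus = seq(0.90, 0.99, by = 0.01),
                             n_boot = 200, exclude_field_mc = TRUE) {
  stopifnot(inherits(samples, "kin_samples"))
  config <- list(epsilon = epsilon, error_mode = error_mode,
                 cutoffs = cutoffs, cutoff = cutoff, n_sim = n_sim,
                 seed = seed, sector_wilcoxon = sector_wilcoxon,
                 sector_qr = sector_qr, taus = taus, n_boot = n_boot,
                 exclude_field_mc = exclude_field_mc)

  dd <- deduplicate(samples,
                    model = kin_model(samples, epsilon = epsilon,
                                      error_mode = error_mode),
                    seed = seed + 11L)
  uniq <- dd$samples
  freqs <- estimate_allele_freqs(uniq)
  hwe <- hwe_check(uniq, freqs)
  model <- kin_model(freqs, epsilon = epsilon, error_mode = error_mode)
  pairs <- predict(model, uniq)

  sim_u <- simulate(model, nsim = n_sim, seed = seed + 21L, category = "U")
  sim_po <- simulate(model, nsim = n_sim, seed = seed + 22L, category = "PO")
  sim_hs <- simulate(model, nsim = n_sim, seed = seed + 23L, category = "HS")
  rates <- error_rates(sim_u, sim_po, cutoffs = cutoffs)
  ctab <- build_cutoff_table(pairs, rates, n_pairs_total = nrow(pairs))

  dyads <- select_dyads(pairs, uniq, scored = "PO", cutoff = cutoff)
  triads <- build_triads(dyads)
  elapsed <- elapsed_time_summary(dyads)

  sp_all <- make_spatial_pairs(pairs, uniq, sector = NULL,
                               exclude_field_mc = exclude_field_mc)
  sp_sector <- make_spatial_pairs(pairs, uniq, sector = sector_wilcoxon,
                                  exclude_field_mc = exclude_field_mc)
  wil <- list(full = wilcoxon_delta_lon(sp_all),
              sector = wilcoxon_delta_lon(sp_sector))
  sp_qr <- make_spatial_pairs(pairs, uniq, sector = sector_qr,
                              exclude_field_mc = exclude_field_mc)
  qr <- quantile_regression(sp_qr, taus = taus, n_boot = n_boot,
                            seed = seed + 31L)
  hs_median <- stats::median(sim_hs$lod_HS)
  ec <- ecdf_compare(sp_qr, ref_lod = hs_median)

  summary <- list(
    n_records = dd$n_input, n_unique = dd$n_unique,
    n_pairs = nrow(pairs), n_dyads = nrow(dyads),
    n_dyads_po = sum(dyads$ml_category == "PO"),
    n_triads = length(triads),
    n_spatial_pairs_full = nrow(sp_all),
    n_spatial_pairs_sector = nrow(sp_sector),
    ml_counts = as.list(table(pairs$ml_category)),
    sim_hs_median_lod_hs = hs_median,
    max_elapsed_years = attr(elapsed, "max_years"))

  out <- structure(list(dedup = dd, freqs = freqs, hwe = hwe, model = model,
                        pairs = pairs, cutoff_table = ctab, dyads = dyads,
                        triads = triads, elapsed = elapsed, wilcoxon = wil,
                        qr = qr, ecdf = ec, summary = summary,
                        config = config),
                   class = "kin_pipeline")
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  invisible(out)
}

.write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE, na = "")
  w(x$dedup$groups, "dedup_groups.csv")
  w(x$hwe, "hwe.csv")
  freq_report <- lapply(x$freqs, function(l)
    list(alleles = l$alleles, freqs = l$freqs, n_typed = l$n_typed))
  jsonlite::write_json(freq_report, file.path(out_dir, "allele_freqs.json"),
                       auto_unbox = TRUE, digits = NA)
  w(x$pairs, "pair_scores.csv")
  w(as.data.frame(x$cutoff_table), "cutoff_table.csv")
  dy <- as.data.frame(x$dyads)
  dy$date_i <- format(dy$date_i); dy$date_j <- format(dy$date_j)
  w(dy, "dyads.csv")
  if (length(x$triads)) {
    edges <- do.call(rbind, lapply(seq_along(x$triads), function(i)
      cbind(triad = i, x$triads[[i]]$edges)))
    w(edges, "triads.csv")
  }
  el <- x$elapsed
  el$first_date <- format(el$first_date); el$second_date <- format(el$second_date)
  w(el, "elapsed_time.csv")
  w(as.data.frame(x$qr), "quantile_regression.csv")
  jsonlite::write_json(
    list(summary = x$summary, config = x$config,
         wilcoxon = x$wilcoxon),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(x)
}

#' @export
print.kin_pipeline <- function(x, ...) {
  s <- x$summary
  cat("close-kin pipeline run\n")
  cat(sprintf("  %d records -> %d individuals -> %d pairwise LOD scores\n",
              s$n_records, s$n_unique, s$n_pairs))
  cat(sprintf("  dyads at LOD_PO > %g: %d (%d ML-classified PO); %d triad group(s)\n",
              x$config$cutoff, s$n_dyads, s$n_dyads_po, s$n_triads))
  cat(sprintf("  rank-sum p (full / sector): %.3g / %.3g\n",
              x$wilcoxon$full$p_value, x$wilcoxon$sector$p_value))
  invisible(x)
}
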