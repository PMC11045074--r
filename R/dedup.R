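#' Detect duplicate and resampled individuals
#'
#' Scores every pair of sample records under the self/monozygotic
#' hypothesis (LOD of SELF versus unrelated) and merges pairs exceeding a
#' threshold into one individual. Merged groups whose records all share the
#' same sampling date and position are tagged
#' \code{"same_place_time_duplicate"} (two biopsies of the same animal at
#' the same encounter); other groups are tagged \code{"resample"} (the same
#' animal sampled at different places/times). One record per individual is
#' retained: the earliest sampling date, ties broken by input order.
#'
#' The default threshold is calibrated by Monte Carlo: unrelated pairs are
#' simulated from the model and the threshold is set at the smallest value
#' for which the expected number of unrelated pairs exceeding it, in a
#' dataset with this many pairwise comparisons, is below
#' \code{fp_budget}. The self-LOD of a true duplicate grows with the number
#' of typed loci and sits far above this, so modest genotyping error does
#' not break matching.
#'
#' @param samples a [kin_samples] object.
#' @param model optional [kin_model]; fitted on \code{samples} (provisional
#'   allele frequencies, duplicates included) when omitted. Re-estimate
#'   frequencies on the unique individuals for downstream scoring.
#' @param threshold self-LOD merge threshold; calibrated when \code{NULL}.
#' @param fp_budget expected false-positive merges tolerated dataset-wide
#'   when calibrating.
#' @param n_sim simulated unrelated pairs used for calibration.
#' @param seed RNG seed for calibration.
#' @return An object of class \code{kin_dedup}: list with
#'   \code{samples} (unique individuals, a [kin_samples]), \code{groups}
#'   (data frame of merged records: \code{individual}, \code{sample_id},
#'   \code{kept}, \code{type}), \code{threshold}, \code{n_input},
#'   \code{n_unique}.
#' @export
deduplicate <- function(samples, model = NULL, threshold = NULL,
                        fp_budget = 0.01, n_sim = 20000, seed = 1) {
  stopifnot(inherits(samples, "kin_samples"))
  if (is.null(model)) model <- kin_model(samples)
  n <- nrow(samples$geno)
  pairs <- predict(model, samples, include_self = TRUE)
  if (is.null(threshold)) {
    threshold <- dedup_threshold(model, n_pairs = nrow(pairs),
                                 fp_budget = fp_budget, n_sim = n_sim,
                                 seed = seed)
  }
  # merge only pairs whose self-LOD clears the threshold AND for which
  # self/monozygotic is the maximum-likelihood hypothesis — a true
  # parent-offspring pair can have a moderately high self-LOD, but its PO
  # LOD is higher still
  ml_self <- !is.na(pairs$lod_SELF) &
    pairs$lod_SELF >= pmax(0, pairs$lod_PO, pairs$lod_FS, pairs$lod_HS)
  hit <- which(ml_self & pairs$lod_SELF > threshold)
  ids <- samples$meta$sample_id
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs$id_i[hit], to = pairs$id_j[hit]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]

  keep <- logical(n)
  grp_rows <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) { keep[members] <- TRUE; next }
    d <- samples$meta$date[members]
    ord <- order(d, members, na.last = TRUE)
    rep_row <- members[ord[1]]
    keep[rep_row] <- TRUE
    same_pos <- length(unique(paste(samples$meta$date[members],
                                    samples$meta$lat[members],
                                    samples$meta$lon[members]))) == 1L
    grp_rows[[length(grp_rows) + 1L]] <- data.frame(
      individual = ids[rep_row], sample_id = ids[members],
      kept = members == rep_row,
      type = if (same_pos) "same_place_time_duplicate" else "resample",
      stringsAsFactors = FALSE)
  }
  groups <- if (length(grp_rows)) do.call(rbind, grp_rows) else
    data.frame(individual = character(), sample_id = character(),
               kept = logical(), type = character(), stringsAsFactors = FALSE)
  structure(list(samples = .subset_samples(samples, which(keep)),
                 groups = groups, threshold = threshold,
                 n_input = n, n_unique = sum(keep)),
            class = "kin_dedup")
}

#' Calibrate the duplicate-detection self-LOD threshold
#'
#' Simulates unrelated pairs under the fitted model, applies the same joint
#' merge criterion as [deduplicate()] (self-LOD above the threshold
#' \emph{and} self/monozygotic the maximum-likelihood hypothesis), and
#' returns the smallest threshold at which the expected number of false
#' merges, scaled to \code{n_pairs} comparisons, stays below
#' \code{fp_budget}. The threshold is floored at 0: a merged pair must at
#' minimum be likelier under self than under unrelatedness.
#'
#' @param model a [kin_model].
#' @param n_pairs number of pairwise comparisons in the target dataset.
#' @param fp_budget tolerated expected false-positive merges.
#' @param n_sim number of simulated unrelated pairs.
#' @param seed RNG seed.
#' @return The threshold (natural-log units).
#' @export
dedup_threshold <- function(model, n_pairs, fp_budget = 0.01,
                            n_sim = 20000, seed = 1) {
  sim <- simulate(model, nsim = n_sim, seed = seed, category = "U",
                  include_self = TRUE)
  ml_self <- sim$lod_SELF >= pmax(0, sim$lod_PO, sim$lod_FS, sim$lod_HS)
  v <- sort(sim$lod_SELF[ml_self])
  if (!length(v)) return(0)
  # expected false merges at threshold v[k]: n_pairs * (count above) / n_sim
  exp_fp <- n_pairs * (length(v) - seq_along(v)) / n_sim
  ok <- which(exp_fp < fp_budget)
  thr <- if (!length(ok)) v[length(v)] + 1 else v[ok[1]]
  max(thr, 0)
}

#' @export
print.kin_dedup <- function(x, ...) {
  nd <- sum(!duplicated(x$groups$individual) &
              x$groups$type == "same_place_time_duplicate")
  nr <- sum(!duplicated(x$groups$individual) & x$groups$type == "resample")
  cat(sprintf("kin_dedup: %d records -> %d unique individuals\n",
              x$n_input, x$n_unique))
  cat(sprintf("  %d same-place/time duplicate group(s), %d resample group(s); self-LOD threshold %.2f\n",
              nd, nr, x$threshold))
  invisible(x)
}
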