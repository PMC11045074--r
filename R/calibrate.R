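#' Simulate LOD-score distributions from a fitted kinship model
#'
#' Draws genotype pairs of a given true kinship category from the model's
#' allele frequencies (per locus: an identity-by-descent state is drawn
#' from the category's Cotterman coefficients, shared alleles are copied,
#' non-shared alleles are independent Hardy-Weinberg draws), pushes both
#' genotypes through the per-allele error channel, and scores every pair
#' under PO, FS and HS (and optionally SELF). This is the Monte-Carlo
#' engine behind cut-off calibration and false-positive/negative
#' accounting.
#'
#' @param object a fitted [kin_model].
#' @param nsim number of genotype pairs to simulate.
#' @param seed RNG seed (required for reproducibility; \code{NULL} leaves
#'   the RNG state alone).
#' @param category true generating category: \code{"U"}, \code{"PO"},
#'   \code{"FS"}, \code{"HS"} or \code{"SELF"}.
#' @param include_self also score the SELF hypothesis.
#' @param ... unused.
#' @return A data frame of class \code{lod_sim} with columns
#'   \code{lod_PO}, \code{lod_FS}, \code{lod_HS} (plus \code{lod_SELF} if
#'   requested) and \code{ml_category}; attributes \code{category} and
#'   \code{seed}.
#' @examples
#' m <- kin_model(locus_model(1:2, c(0.5, 0.5)), epsilon = 0)
#' sim <- simulate(m, nsim = 1000, seed = 1, category = "PO")
#' mean(sim$lod_PO)
#' @export
simulate.kin_model <- function(object, nsim = 1, seed = NULL,
                               category = "U", include_self = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  kap <- .kappa(category)
  hyps <- c("PO", "FS", "HS", if (include_self) "SELF")
  lods <- matrix(0, nsim, length(hyps), dimnames = list(NULL, hyps))
  eps <- object$epsilon
  for (t in object$tables) {
    k <- length(t$alleles)
    p <- t$freqs
    z <- sample.int(3L, nsim, replace = TRUE, prob = kap) - 1L
    s1 <- sample.int(k, nsim, replace = TRUE, prob = p)
    s2 <- sample.int(k, nsim, replace = TRUE, prob = p)
    x1 <- sample.int(k, nsim, replace = TRUE, prob = p)
    x2 <- sample.int(k, nsim, replace = TRUE, prob = p)
    y1 <- sample.int(k, nsim, replace = TRUE, prob = p)
    y2 <- sample.int(k, nsim, replace = TRUE, prob = p)
    # genotype of individual 1: (a1, a2); individual 2: (b1, b2)
    a1 <- ifelse(z >= 1L, s1, x1)
    a2 <- ifelse(z == 2L, s2, x2)
    b1 <- ifelse(z >= 1L, s1, y1)
    b2 <- ifelse(z == 2L, s2, y2)
    if (eps > 0 && k > 1) {
      a1 <- .apply_allele_error(a1, k, p, eps, object$error_mode)
      a2 <- .apply_allele_error(a2, k, p, eps, object$error_mode)
      b1 <- .apply_allele_error(b1, k, p, eps, object$error_mode)
      b2 <- .apply_allele_error(b2, k, p, eps, object$error_mode)
    }
    gi <- t$gidx[cbind(a1, a2)]
    gj <- t$gidx[cbind(b1, b2)]
    idx <- cbind(gi, gj)
    for (h in hyps) lods[, h] <- lods[, h] + t$logR[[h]][idx]
  }
  out <- as.data.frame(lods)
  names(out) <- paste0("lod_", hyps)
  out$ml_category <- .ml_category(lods[, c("PO", "FS", "HS"), drop = FALSE])
  attr(out, "category") <- category
  attr(out, "seed") <- seed
  class(out) <- c("lod_sim", "data.frame")
  out
}

# per-allele genotyping error: with probability eps replace the called
# allele by a population-frequency draw (freq_draw; self-replacement
# allowed) or by a uniform draw among the other alleles (uniform_other)
.apply_allele_error <- function(a, k, p, eps, mode) {
  n <- length(a)
  err <- stats::runif(n) < eps
  ne <- sum(err)
  if (!ne) return(a)
  if (mode == "freq_draw") {
    a[err] <- sample.int(k, ne, replace = TRUE, prob = p)
  } else {
    r <- sample.int(k - 1L, ne, replace = TRUE)
    a[err] <- r + (r >= a[err])
  }
  a
}

#' False-positive and false-negative rates on a cut-off grid
#'
#' For each scored hypothesis (LOD_PO and/or LOD_HS), cut-off value and
#' kinship category, the false-positive rate is the fraction of simulated
#' unrelated pairs whose scored LOD exceeds the cut-off \emph{and} whose
#' maximum-likelihood category is that category. The false-negative rate
#' (reported for the PO category) is the fraction of simulated true PO
#' pairs failing that joint criterion.
#'
#' @param sim_u a \code{lod_sim} of simulated unrelated pairs.
#' @param sim_po a \code{lod_sim} of simulated parent-offspring pairs.
#' @param cutoffs numeric vector of LOD cut-off values (non-empty).
#' @param scored hypotheses whose LOD is thresholded, subset of
#'   \code{c("PO", "HS")}.
#' @param categories maximum-likelihood categories tabulated.
#' @return Data frame: \code{scored}, \code{cutoff}, \code{category},
#'   \code{fp_rate}, \code{fn_rate} (\code{NA} outside the PO category).
#' @export
error_rates <- function(sim_u, sim_po, cutoffs, scored = c("PO", "HS"),
                        categories = c("FS", "HS", "PO")) {
  if (!length(cutoffs)) stop("cutoff grid is empty")
  grid <- expand.grid(scored = scored, cutoff = cutoffs,
                      category = categories, stringsAsFactors = FALSE)
  grid$fp_rate <- NA_real_
  grid$fn_rate <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sc <- paste0("lod_", grid$scored[r])
    cu <- grid$cutoff[r]; ca <- grid$category[r]
    grid$fp_rate[r] <- mean(sim_u[[sc]] > cu & sim_u$ml_category == ca)
    if (ca == "PO")
      grid$fn_rate[r] <- mean(!(sim_po[[sc]] > cu & sim_po$ml_category == "PO"))
  }
  grid
}

#' Build a cut-off table of observed and expected kin counts
#'
#' Mirrors the standard presentation of close-kin screening: for each
#' scored hypothesis, cut-off and maximum-likelihood category, the number
#' of data pairs passing, the expected number of false positives
#' (per-pair simulated rate times the total number of comparisons, all
#' pairs being a priori unrelated to good approximation), and — for the PO
#' category — the expected number of false negatives, scaled by the
#' bias-corrected PO count obtained from the fixed point of
#' [corrected_kin_count()].
#'
#' @param pairs a \code{kin_pairs} data frame of scored data pairs.
#' @param rates output of [error_rates()] computed with the same model.
#' @param n_pairs_total number of pairwise comparisons (defaults to
#'   \code{nrow(pairs)}).
#' @return Data frame of class \code{cutoff_table}: \code{scored},
#'   \code{cutoff}, \code{category}, \code{observed}, \code{expected_fp},
#'   \code{fn_rate}, \code{expected_fn}, \code{corrected}.
#' @export
build_cutoff_table <- function(pairs, rates, n_pairs_total = nrow(pairs)) {
  out <- rates
  out$observed <- NA_integer_
  out$expected_fp <- out$fp_rate * n_pairs_total
  out$expected_fn <- NA_real_
  out$corrected <- NA_real_
  for (r in seq_len(nrow(out))) {
    sc <- paste0("lod_", out$scored[r])
    v <- pairs[[sc]]
    out$observed[r] <- sum(!is.na(v) & v > out$cutoff[r] &
                             pairs$ml_category == out$category[r])
    if (out$category[r] == "PO" && !is.na(out$fn_rate[r]) && out$fn_rate[r] < 1) {
      cc <- corrected_kin_count(out$observed[r], out$expected_fp[r],
                                fn_rate = out$fn_rate[r])
      out$corrected[r] <- cc
      out$expected_fn[r] <- out$fn_rate[r] * cc
    }
  }
  out <- out[, c("scored", "cutoff", "category", "observed", "expected_fp",
                 "fn_rate", "expected_fn", "corrected")]
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Bias-corrected kin count
#'
#' Unbiased estimate of the true number of kin pairs: the observed count
#' minus the expected false positives plus the expected false negatives.
#' When the expected false-negative count is supplied directly the result
#' is plain arithmetic. When only a false-negative \emph{rate} is known,
#' the expected false negatives scale with the unknown true count, and the
#' estimate is the fixed point of
#' \code{N = observed - expected_fp + fn_rate * N}, iterated to a relative
#' tolerance of 1e-6.
#'
#' @param observed observed kin-pair count (>= 0).
#' @param expected_fp expected false positives (>= 0).
#' @param expected_fn expected false negatives, if known as a count.
#' @param fn_rate per-true-pair false-negative rate in \[0, 1), if the
#'   count is unknown.
#' @param tol relative tolerance of the fixed-point iteration.
#' @param max_iter iteration cap.
#' @return The corrected count (may be negative, with a warning).
#' @examples
#' corrected_kin_count(25, 4, expected_fn = 8)   # 29
#' @export
corrected_kin_count <- function(observed, expected_fp, expected_fn = NULL,
                                fn_rate = NULL, tol = 1e-6, max_iter = 1000) {
  stopifnot(observed >= 0, expected_fp >= 0)
  if (!is.null(expected_fn)) {
    out <- observed - expected_fp + expected_fn
  } else {
    if (is.null(fn_rate)) stop("supply expected_fn or fn_rate")
    if (fn_rate < 0 || fn_rate >= 1) stop("fn_rate must be in [0, 1)")
    n <- max(observed - expected_fp, 0)
    for (i in seq_len(max_iter)) {
      n_new <- observed - expected_fp + fn_rate * n
      if (abs(n_new - n) <= tol * max(1, abs(n_new))) { n <- n_new; break }
      n <- n_new
    }
    out <- n
  }
  if (out < 0) warning("corrected kin count is negative (", signif(out, 3), ")")
  out
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat("cutoff_table (observed counts with expected false positives; expected\n")
  cat("false negatives reported for the PO category):\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
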