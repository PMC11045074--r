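#' Score all pairs of individuals
#'
#' Computes LOD scores for every unordered pair of samples under the
#' parent-offspring, full-sibling and half-sibling hypotheses (optionally
#' also self/monozygotic, used by duplicate detection) and assigns the
#' maximum-likelihood kinship category among \{PO, FS, HS, U\}. LOD under
#' unrelatedness is identically zero, so the ML category is the hypothesis
#' with the largest LOD; ties are broken toward the less related category
#' (U before HS before FS before PO).
#'
#' @param object a fitted [kin_model].
#' @param samples a [kin_samples] object typed at the model's loci.
#' @param include_self also score the SELF hypothesis (column
#'   \code{lod_SELF}).
#' @param ... unused.
#' @return A data frame of class \code{kin_pairs} with one row per
#'   unordered pair: \code{id_i}, \code{id_j}, \code{lod_PO},
#'   \code{lod_FS}, \code{lod_HS} (and \code{lod_SELF} if requested),
#'   \code{n_loci}, \code{ml_category}. Pairs sharing no typed locus have
#'   \code{NA} LODs and \code{ml_category} \code{"unscorable"}.
#' @examples
#' sim <- simulate_population(sim_config(n_unrelated = 8, n_po = 1,
#'   n_hs = 0, n_fs = 0, n_triads = 0, n_duplicates = 0, n_resamples = 0,
#'   n_mc_pairs = 0, seed = 7))
#' m <- kin_model(sim$samples)
#' head(predict(m, sim$samples))
#' @export
predict.kin_model <- function(object, samples, include_self = FALSE, ...) {
  stopifnot(inherits(samples, "kin_samples"))
  n <- nrow(samples$geno)
  if (n < 2) stop("need at least two samples to form pairs")
  G <- .geno_index_matrix(object, samples)
  ii <- rep.int(seq_len(n - 1), (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  hyps <- c("PO", "FS", "HS", if (include_self) "SELF")
  np <- length(ii)
  lods <- matrix(0, np, length(hyps), dimnames = list(NULL, hyps))
  used <- integer(np)
  for (l in seq_len(ncol(G))) {
    gi <- G[ii, l]; gj <- G[jj, l]
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok)) next
    used <- used + ok
    idx <- cbind(gi[ok], gj[ok])
    t <- object$tables[[l]]
    for (h in hyps) lods[ok, h] <- lods[ok, h] + t$logR[[h]][idx]
  }
  ml <- .ml_category(lods[, c("PO", "FS", "HS"), drop = FALSE])
  ml[used == 0L] <- "unscorable"
  lods[used == 0L, ] <- NA_real_
  out <- data.frame(id_i = samples$meta$sample_id[ii],
                    id_j = samples$meta$sample_id[jj],
                    stringsAsFactors = FALSE)
  for (h in hyps) out[[paste0("lod_", h)]] <- lods[, h]
  out$n_loci <- used
  out$ml_category <- ml
  class(out) <- c("kin_pairs", "data.frame")
  out
}

# maximum-likelihood category over {PO, FS, HS, U}; lod_U = 0; ties broken
# toward the less related label (assigned last below, so it wins ties)
.ml_category <- function(lods) {
  m <- cbind(U = 0, lods[, c("HS", "FS", "PO"), drop = FALSE])
  best <- pmax(m[, "U"], m[, "HS"], m[, "FS"], m[, "PO"])
  out <- rep(NA_character_, nrow(m))
  for (lab in rev(.ML_PRIORITY)) out[m[, lab] == best] <- lab
  out
}

#' @export
print.kin_pairs <- function(x, ...) {
  cat(sprintf("kin_pairs: %d pairwise LOD scores\n", nrow(x)))
  print(table(ml_category = x$ml_category))
  invisible(x)
}
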