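#' Kinship hypotheses and their identity-by-descent coefficients
#'
#' Returns the catalogue of pairwise kinship hypotheses used throughout the
#' package, each with its Cotterman coefficient vector \eqn{(\kappa_0,
#' \kappa_1, \kappa_2)}: the probabilities that a pair shares 0, 1 or 2
#' alleles identical by descent at an autosomal locus.
#'
#' The second-degree relationships half-sibling, grandparent-grandchild and
#' avuncular share the same coefficients (1/2, 1/2, 0) and are therefore
#' indistinguishable from pairwise genotypes alone; they are collectively
#' labelled \code{"HS"}. \code{"SELF"} (same individual, or monozygotic
#' twins) is used only for duplicate detection.
#'
#' @param labels optional character vector to subset, e.g. \code{c("PO","U")}.
#' @return A data frame with columns \code{label}, \code{k0}, \code{k1},
#'   \code{k2} and \code{notes}.
#' @examples
#' kin_hypotheses()
#' @export
kin_hypotheses <- function(labels = NULL) {
  h <- data.frame(
    label = c("U", "PO", "FS", "HS", "SELF"),
    k0 = c(1, 0, 1 / 4, 1 / 2, 0),
    k1 = c(0, 1, 1 / 2, 1 / 2, 0),
    k2 = c(0, 0, 1 / 4, 0, 1),
    notes = c(
      "unrelated",
      "parent-offspring",
      "full sibling",
      "half sibling; also grandparent-grandchild and avuncular",
      "same individual / monozygotic"
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(labels)) {
    bad <- setdiff(labels, h$label)
    if (length(bad)) stop("unknown kinship label(s): ", paste(bad, collapse = ", "))
    h <- h[match(labels, h$label), , drop = FALSE]
    rownames(h) <- NULL
  }
  h
}

# kappa vector for a single label
.kappa <- function(label) {
  h <- kin_hypotheses(label)
  c(h$k0, h$k1, h$k2)
}

# tie-break priority for maximum-likelihood classification: ties go to the
# less related category
.ML_PRIORITY <- c("U", "HS", "FS", "PO")
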