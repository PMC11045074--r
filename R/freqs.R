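#' Estimate population allele frequencies per locus
#'
#' Frequencies are simple allele counts divided by the total number of typed
#' alleles at each locus; samples missing a locus contribute nothing there.
#' The result is the frequency model used by all downstream likelihoods
#' (kinship LODs, cut-off simulation, duplicate detection).
#'
#' @param x a [kin_samples] object.
#' @return An object of class \code{locus_freqs}: a list with one element
#'   per locus, each a list with \code{name}, \code{alleles} (sorted integer
#'   labels), \code{freqs} (summing to 1), \code{n_typed} (number of typed
#'   gene copies) and \code{monomorphic}.
#' @examples
#' s <- simulate_population(sim_config(n_unrelated = 30, n_po = 0, n_hs = 0,
#'                                     n_fs = 0, n_triads = 0, n_duplicates = 0,
#'                                     n_resamples = 0, n_mc_pairs = 0, seed = 1))
#' f <- estimate_allele_freqs(s$samples)
#' f[[1]]
#' @export
estimate_allele_freqs <- function(x) {
  stopifnot(inherits(x, "kin_samples"))
  out <- vector("list", length(x$loci))
  for (l in seq_along(x$loci)) {
    al <- c(x$geno[, 2 * l - 1], x$geno[, 2 * l])
    al <- al[!is.na(al)]
    if (!length(al)) stop("locus ", x$loci[l], " has no typed alleles")
    tab <- table(al)
    alleles <- as.integer(names(tab))
    freqs <- as.numeric(tab) / length(al)
    out[[l]] <- list(name = x$loci[l], alleles = alleles, freqs = freqs,
                     n_typed = length(al), monomorphic = length(alleles) == 1L)
  }
  names(out) <- x$loci
  structure(out, class = "locus_freqs")
}

#' Build a single-locus frequency model directly
#'
#' Convenience constructor for a one-locus allele frequency model, mainly
#' for worked examples and simulation from known truth.
#'
#' @param alleles integer allele labels.
#' @param freqs probability vector over \code{alleles} (must sum to 1).
#' @param name locus label.
#' @return A \code{locus_freqs} object of length one.
#' @examples
#' locus_model(1:2, c(0.5, 0.5))
#' @export
locus_model <- function(alleles, freqs, name = "L1") {
  alleles <- as.integer(alleles)
  if (length(alleles) != length(freqs)) stop("alleles and freqs lengths differ")
  if (any(freqs <= 0)) stop("all allele frequencies must be > 0")
  if (abs(sum(freqs) - 1) > 1e-12) stop("freqs must sum to 1")
  o <- order(alleles)
  structure(list(list(name = name, alleles = alleles[o], freqs = freqs[o],
                      n_typed = NA_integer_,
                      monomorphic = length(alleles) == 1L)),
            class = "locus_freqs")
}

#' @export
`[.locus_freqs` <- function(x, i) {
  structure(unclass(x)[i], class = "locus_freqs")
}

#' Combine several single-locus models into one frequency model
#' @param ... \code{locus_freqs} objects (or lists of per-locus entries).
#' @return A \code{locus_freqs} object.
#' @export
c.locus_freqs <- function(...) {
  parts <- list(...)
  out <- unlist(lapply(parts, unclass), recursive = FALSE)
  names(out) <- vapply(out, `[[`, character(1), "name")
  structure(out, class = "locus_freqs")
}

#' @export
print.locus_freqs <- function(x, ...) {
  cat(sprintf("locus_freqs: %d loci, %d-%d alleles per locus\n", length(x),
              min(vapply(x, function(l) length(l$alleles), integer(1))),
              max(vapply(x, function(l) length(l$alleles), integer(1)))))
  invisible(x)
}

#' Hardy-Weinberg equilibrium check per locus
#'
#' Chi-square goodness-of-fit of observed genotype counts against the
#' Hardy-Weinberg expectations implied by the estimated allele frequencies.
#' Genotype classes with small expected counts are pooled (smallest classes
#' merged until every class expectation is at least \code{min_expected}),
#' and the degrees of freedom are \code{#classes - #alleles}, clipped at 1,
#' accounting for the allele frequencies having been estimated from the same
#' data. A monomorphic locus is reported as not testable rather than as an
#' error.
#'
#' @param x a [kin_samples] object.
#' @param freqs optional \code{locus_freqs}; estimated from \code{x} if
#'   omitted.
#' @param pool pool rare genotype classes before the test (default TRUE).
#' @param min_expected pooling threshold on expected class counts.
#' @return Data frame with one row per locus: \code{locus}, \code{n},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{n_classes},
#'   \code{testable}.
#' @export
hwe_check <- function(x, freqs = NULL, pool = TRUE, min_expected = 5) {
  stopifnot(inherits(x, "kin_samples"))
  if (is.null(freqs)) freqs <- estimate_allele_freqs(x)
  res <- lapply(seq_along(x$loci), function(l) {
    lm <- freqs[[l]]
    a1 <- x$geno[, 2 * l - 1]; a2 <- x$geno[, 2 * l]
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]
    n <- length(a1)
    if (lm$monomorphic || n == 0) {
      return(data.frame(locus = lm$name, n = n, statistic = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        n_classes = NA_integer_, testable = FALSE))
    }
    k <- length(lm$alleles)
    gi <- .geno_pairs(k)
    p <- lm$freqs
    expp <- ifelse(gi[, 1] == gi[, 2], p[gi[, 1]]^2, 2 * p[gi[, 1]] * p[gi[, 2]])
    i1 <- match(pmin(a1, a2), lm$alleles)
    i2 <- match(pmax(a1, a2), lm$alleles)
    gidx <- .gidx_matrix(k)[cbind(i1, i2)]
    obs <- tabulate(gidx, nbins = nrow(gi))
    expc <- expp * n
    if (pool) {
      # merge smallest-expectation classes until all pooled classes >= threshold
      grp <- seq_along(expc)
      o <- order(expc)
      pool_members <- integer(0)
      for (j in o) {
        if (expc[j] >= min_expected && !length(pool_members)) break
        pool_members <- c(pool_members, j)
        if (sum(expc[pool_members]) >= min_expected) break
      }
      # keep pooling any remaining small classes into the pooled class
      small <- setdiff(which(expc < min_expected), pool_members)
      pool_members <- union(pool_members, small)
      if (length(pool_members) > 1) {
        obs <- c(obs[-pool_members], sum(obs[pool_members]))
        expc <- c(expc[-pool_members], sum(expc[pool_members]))
      }
    }
    stat <- sum((obs - expc)^2 / expc)
    df <- max(length(obs) - k, 1L)
    data.frame(locus = lm$name, n = n, statistic = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE),
               n_classes = length(obs), testable = TRUE)
  })
  do.call(rbind, res)
}

# unordered genotype enumeration for k alleles: rows (i, j), i <= j, in the
# canonical package order
.geno_pairs <- function(k) {
  i <- rep(seq_len(k), times = k - seq_len(k) + 1)
  j <- unlist(lapply(seq_len(k), function(a) a:k))
  cbind(i, j)
}

# k x k symmetric matrix mapping an (allele index, allele index) pair to its
# unordered genotype index in .geno_pairs order
.gidx_matrix <- function(k) {
  gp <- .geno_pairs(k)
  m <- matrix(NA_integer_, k, k)
  m[gp] <- seq_len(nrow(gp))
  m[gp[, c(2, 1), drop = FALSE]] <- seq_len(nrow(gp))
  m
}
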