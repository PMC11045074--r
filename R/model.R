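#' Fit the pairwise kinship likelihood model
#'
#' This is the package's central fitting function. From a sample table (or a
#' ready-made allele frequency model) it builds, for every locus, the full
#' table of observed-genotype-pair probabilities
#' \deqn{P(G_i, G_j \mid K) = \sum_{g_i, g_j} P(g_i, g_j \mid K)\,
#'       P(G_i \mid g_i)\, P(G_j \mid g_j)}
#' under each kinship hypothesis \eqn{K} (unrelated, parent-offspring, full
#' sibling, half sibling, self), where the true-pair probability decomposes
#' over the Cotterman coefficients
#' \deqn{P(g_i, g_j \mid K) = \kappa_0 P(g_i) P(g_j) +
#'       \kappa_1 P(g_i) T(g_j \mid g_i) + \kappa_2 P(g_i) 1[g_i = g_j],}
#' with \eqn{P(\cdot)} the Hardy-Weinberg genotype probability and
#' \eqn{T} the one-shared-allele (Mendelian parent-offspring) transition.
#' Genotyping error enters through a constant, independent per-allele error
#' rate \eqn{\epsilon}: each observed allele equals the true allele with
#' probability \eqn{1-\epsilon} and is otherwise replaced by a random allele
#' (drawn from the population frequencies in mode \code{"freq_draw"},
#' uniformly among the other alleles in mode \code{"uniform_other"}).
#' With \eqn{\epsilon > 0} every genotype pair has positive probability
#' under every hypothesis, so LOD scores are finite even for
#' Mendelian-incompatible pairs.
#'
#' The returned object supports [predict.kin_model()] (score all pairs),
#' [simulate.kin_model()] (Monte-Carlo LOD distributions), \code{print} and
#' \code{summary}.
#'
#' @param x a [kin_samples] object (allele frequencies are estimated from
#'   it) or a \code{locus_freqs} object.
#' @param epsilon per-allele genotyping error rate in \[0, 0.5).
#' @param error_mode \code{"freq_draw"} (mis-called allele drawn from the
#'   population frequencies, self-replacement allowed) or
#'   \code{"uniform_other"} (uniform over the other alleles).
#' @return An object of class \code{kin_model}.
#' @examples
#' f <- locus_model(1:2, c(0.5, 0.5))
#' m <- kin_model(f, epsilon = 0)
#' pair_lod(m, c(1, 1), c(1, 1), "PO")   # ln 2
#' @export
kin_model <- function(x, epsilon = 0.0077,
                      error_mode = c("freq_draw", "uniform_other")) {
  error_mode <- match.arg(error_mode)
  if (inherits(x, "kin_samples")) x <- estimate_allele_freqs(x)
  if (!inherits(x, "locus_freqs")) stop("x must be kin_samples or locus_freqs")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  hyps <- kin_hypotheses()
  tables <- lapply(x, .locus_tables, epsilon = epsilon, mode = error_mode,
                   hyps = hyps)
  names(tables) <- names(x)
  structure(list(freqs = x, epsilon = epsilon, error_mode = error_mode,
                 hypotheses = hyps, tables = tables),
            class = "kin_model")
}

# all per-locus machinery: HWE vector, PO transition, genotype-level error
# matrix, observed-pair probability matrix per hypothesis and the log-ratio
# tables used for scoring
.locus_tables <- function(lm, epsilon, mode, hyps) {
  k <- length(lm$alleles)
  p <- lm$freqs
  gp <- .geno_pairs(k)
  ng <- nrow(gp)
  hwe <- ifelse(gp[, 1] == gp[, 2], p[gp[, 1]]^2, 2 * p[gp[, 1]] * p[gp[, 2]])

  # T[g1, g2] = P(offspring genotype g2 | parent genotype g1): the parent
  # transmits one of its two alleles with probability 1/2 each, the other
  # parental contribution is a population draw
  Tm <- matrix(0, ng, ng)
  for (g1 in seq_len(ng)) {
    a <- gp[g1, 1]; b <- gp[g1, 2]
    for (g2 in seq_len(ng)) {
      c1 <- gp[g2, 1]; d1 <- gp[g2, 2]
      pr <- 0
      for (t in c(a, b)) { # transmitted allele, prob 1/2 each
        if (c1 == d1) {
          if (t == c1) pr <- pr + 0.5 * p[c1]
        } else {
          if (t == c1) pr <- pr + 0.5 * p[d1]
          if (t == d1) pr <- pr + 0.5 * p[c1]
        }
      }
      Tm[g1, g2] <- pr
    }
  }

  # per-allele error matrix, rows = true allele
  Ea <- if (epsilon == 0 || k == 1) {
    diag(k)
  } else if (mode == "freq_draw") {
    (1 - epsilon) * diag(k) + epsilon * matrix(p, k, k, byrow = TRUE)
  } else {
    (1 - epsilon) * diag(k) + (epsilon / (k - 1)) * (matrix(1, k, k) - diag(k))
  }

  # genotype-level error matrix E[true geno, observed geno]
  Eg <- matrix(0, ng, ng)
  for (gt in seq_len(ng)) {
    a <- gp[gt, 1]; b <- gp[gt, 2]
    for (go in seq_len(ng)) {
      x1 <- gp[go, 1]; y1 <- gp[go, 2]
      Eg[gt, go] <- if (x1 == y1) Ea[a, x1] * Ea[b, x1]
                    else Ea[a, x1] * Ea[b, y1] + Ea[a, y1] * Ea[b, x1]
    }
  }

  # base true-pair matrices for kappa = (1,0,0), (0,1,0), (0,0,1), pushed
  # through the error channel once; any hypothesis is a kappa-combination
  M0 <- tcrossprod(hwe)              # kappa0: independent HWE draws
  M1 <- hwe * Tm                     # kappa1: one allele IBD
  M2 <- diag(hwe)                    # kappa2: both alleles IBD
  # symmetrise so lookups are exactly order-invariant despite rounding
  sym <- function(M) (M + t(M)) / 2
  O0 <- sym(crossprod(Eg, M0 %*% Eg))
  O1 <- sym(crossprod(Eg, M1 %*% Eg))
  O2 <- sym(crossprod(Eg, M2 %*% Eg))

  P <- list(); logR <- list()
  for (i in seq_len(nrow(hyps))) {
    lab <- hyps$label[i]
    P[[lab]] <- hyps$k0[i] * O0 + hyps$k1[i] * O1 + hyps$k2[i] * O2
  }
  for (lab in setdiff(hyps$label, "U")) {
    logR[[lab]] <- log(P[[lab]]) - log(P[["U"]])
  }
  list(name = lm$name, alleles = lm$alleles, freqs = p, geno = gp,
       hwe = hwe, Tmat = Tm, Eallele = Ea, Egeno = Eg, P = P, logR = logR,
       gidx = .gidx_matrix(k))
}

#' @export
print.kin_model <- function(x, ...) {
  cat(sprintf("kin_model: %d loci, per-allele error rate %.4g (%s)\n",
              length(x$tables), x$epsilon, x$error_mode))
  cat("  hypotheses:", paste(x$hypotheses$label, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.kin_model <- function(object, ...) {
  ks <- vapply(object$tables, function(t) length(t$alleles), integer(1))
  # expected per-locus LOD_PO contribution of a true PO pair: a measure of
  # marker informativeness
  info <- vapply(object$tables, function(t)
    sum(t$P$PO * t$logR$PO), numeric(1))
  out <- data.frame(locus = names(object$tables), n_alleles = ks,
                    expected_PO_lod = info, row.names = NULL)
  cat(sprintf("kin_model with %d loci (epsilon = %.4g, %s)\n",
              length(ks), object$epsilon, object$error_mode))
  cat(sprintf("  alleles per locus: %d-%d; total expected LOD_PO for a true PO pair: %.2f\n",
              min(ks), max(ks), sum(info)))
  invisible(out)
}

#' Probability of a true (error-free) genotype pair under a kinship hypothesis
#'
#' Computes \eqn{\kappa_0 P(g_1)P(g_2) + \kappa_1 P(g_1)T(g_2|g_1) +
#' \kappa_2 P(g_1) 1[g_1=g_2]} directly from the allele frequencies; it is
#' symmetric in the two genotypes.
#'
#' @param g1,g2 length-2 vectors of allele labels (unordered).
#' @param locus a \code{locus_freqs} object of length one, or one element of
#'   one.
#' @param hypothesis a kinship label (\code{"U"}, \code{"PO"}, \code{"FS"},
#'   \code{"HS"}, \code{"SELF"}).
#' @return A probability.
#' @examples
#' l <- locus_model(1:2, c(0.5, 0.5))
#' true_pair_prob(c(1, 1), c(1, 1), l, "PO")  # 0.125
#' @export
true_pair_prob <- function(g1, g2, locus, hypothesis) {
  lm <- if (inherits(locus, "locus_freqs")) locus[[1]] else locus
  kap <- .kappa(hypothesis)
  i <- match(g1, lm$alleles); j <- match(g2, lm$alleles)
  if (anyNA(i) || anyNA(j)) stop("allele not in locus catalogue")
  p <- lm$freqs
  hweP <- function(ix) if (ix[1] == ix[2]) p[ix[1]]^2 else 2 * p[ix[1]] * p[ix[2]]
  trans <- function(from, to) {
    pr <- 0
    for (t in from) {
      if (to[1] == to[2]) {
        if (t == to[1]) pr <- pr + 0.5 * p[to[1]]
      } else {
        if (t == to[1]) pr <- pr + 0.5 * p[to[2]]
        if (t == to[2]) pr <- pr + 0.5 * p[to[1]]
      }
    }
    pr
  }
  same <- identical(sort(i), sort(j))
  kap[1] * hweP(i) * hweP(j) + kap[2] * hweP(i) * trans(i, j) +
    kap[3] * hweP(i) * as.numeric(same)
}

#' Probability of an observed genotype pair under a kinship hypothesis
#'
#' Marginalises the true-pair probability over all true genotype pairs
#' through the per-allele error channel of a fitted [kin_model]. Strictly
#' positive whenever the model's error rate is positive.
#'
#' @param g1,g2 length-2 vectors of observed allele labels.
#' @param model a [kin_model].
#' @param locus locus name or index.
#' @param hypothesis kinship label.
#' @return A probability.
#' @export
observed_pair_prob <- function(g1, g2, model, locus = 1, hypothesis = "PO") {
  stopifnot(inherits(model, "kin_model"))
  t <- model$tables[[locus]]
  i <- match(g1, t$alleles); j <- match(g2, t$alleles)
  if (anyNA(i) || anyNA(j)) stop("allele not in locus catalogue")
  t$P[[hypothesis]][t$gidx[i[1], i[2]], t$gidx[j[1], j[2]]]
}

#' LOD score of one genotype pair
#'
#' Natural-log likelihood ratio of two multilocus genotypes under a kinship
#' hypothesis versus unrelatedness, summed over the loci typed in both
#' individuals. \code{lod(U)} is identically zero. With error rate zero a
#' Mendelian-incompatible pair has LOD \code{-Inf} under \code{"PO"} or
#' \code{"SELF"}; a pair with no shared typed locus returns \code{NA}
#' (unscorable).
#'
#' @param model a [kin_model].
#' @param geno_i,geno_j integer vectors of length \code{2 * n_loci} (two
#'   adjacent entries per locus, \code{NA} for missing), in the model's
#'   locus order.
#' @param hypothesis kinship label.
#' @return The LOD score (natural-log units).
#' @export
pair_lod <- function(model, geno_i, geno_j, hypothesis = "PO") {
  stopifnot(inherits(model, "kin_model"))
  if (hypothesis == "U") return(0)
  L <- length(model$tables)
  stopifnot(length(geno_i) == 2 * L, length(geno_j) == 2 * L)
  tot <- 0; used <- 0L
  for (l in seq_len(L)) {
    t <- model$tables[[l]]
    a <- geno_i[c(2 * l - 1, 2 * l)]; b <- geno_j[c(2 * l - 1, 2 * l)]
    if (anyNA(a) || anyNA(b)) next
    i <- match(a, t$alleles); j <- match(b, t$alleles)
    if (anyNA(i) || anyNA(j)) stop("allele not in locus catalogue at ", t$name)
    tot <- tot + t$logR[[hypothesis]][t$gidx[i[1], i[2]], t$gidx[j[1], j[2]]]
    used <- used + 1L
  }
  if (used == 0L) return(NA_real_)
  tot
}

# map a kin_samples genotype matrix to a matrix of per-locus genotype
# indices in the model's tables (n x L, NA where untyped)
.geno_index_matrix <- function(model, samples) {
  L <- length(model$tables)
  stopifnot(length(samples$loci) == L)
  n <- nrow(samples$geno)
  G <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    t <- model$tables[[l]]
    a1 <- match(samples$geno[, 2 * l - 1], t$alleles)
    a2 <- match(samples$geno[, 2 * l], t$alleles)
    typed <- !is.na(samples$geno[, 2 * l - 1])
    if (any(typed & (is.na(a1) | is.na(a2))))
      stop("allele absent from frequency model at locus ", t$name,
           " (was the model fitted on these samples?)")
    ok <- typed
    G[ok, l] <- t$gidx[cbind(a1[ok], a2[ok])]
  }
  G
}
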