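# Independent brute-force oracle for observed genotype-pair probabilities.
#
# Works on ORDERED allele tuples: the true-pair distribution over ordered
# 4-tuples (a1, a2, b1, b2) is assembled by enumerating the IBD state, the
# shared allele(s) and the free Hardy-Weinberg draws, randomising
# within-genotype order explicitly; the error channel is applied per
# ordered allele slot via a Kronecker product; unordered probabilities are
# obtained at the end by summing over orderings. This is a different
# construction from the package's unordered-genotype algebra (which carries
# 2pq-style combinatorial factors throughout), so agreement is a real
# cross-check.

# ordered per-allele error kernel, rows = true allele, cols = observed
.oracle_allele_error_matrix <- function(p, eps, mode) {
  k <- length(p)
  if (eps == 0 || k == 1) return(diag(k))
  if (mode == "freq_draw") {
    (1 - eps) * diag(k) + eps * matrix(p, k, k, byrow = TRUE)
  } else {
    (1 - eps) * diag(k) + (eps / (k - 1)) * (matrix(1, k, k) - diag(k))
  }
}

# distribution over ordered true 4-tuples under kappa, as a k^2 x k^2
# matrix indexed by ordered genotypes (a1-1)*k + a2
.oracle_true_tuple_dist <- function(p, kappa) {
  k <- length(p)
  idx <- function(x, y) (x - 1L) * k + y
  P <- matrix(0, k * k, k * k)
  # z = 0: four independent draws
  if (kappa[1] > 0) {
    for (a1 in 1:k) for (a2 in 1:k) for (b1 in 1:k) for (b2 in 1:k)
      P[idx(a1, a2), idx(b1, b2)] <- P[idx(a1, a2), idx(b1, b2)] +
        kappa[1] * p[a1] * p[a2] * p[b1] * p[b2]
  }
  # z = 1: shared allele s plus free draws x, y; order randomised per genotype
  if (kappa[2] > 0) {
    for (s in 1:k) for (x in 1:k) for (y in 1:k) {
      m <- kappa[2] * p[s] * p[x] * p[y]
      for (a in list(c(s, x), c(x, s))) for (b in list(c(s, y), c(y, s)))
        P[idx(a[1], a[2]), idx(b[1], b[2])] <-
          P[idx(a[1], a[2]), idx(b[1], b[2])] + m / 4
    }
  }
  # z = 2: both genotypes are order-randomised copies of (s1, s2)
  if (kappa[3] > 0) {
    for (s1 in 1:k) for (s2 in 1:k) {
      m <- kappa[3] * p[s1] * p[s2]
      for (a in list(c(s1, s2), c(s2, s1))) for (b in list(c(s1, s2), c(s2, s1)))
        P[idx(a[1], a[2]), idx(b[1], b[2])] <-
          P[idx(a[1], a[2]), idx(b[1], b[2])] + m / 4
    }
  }
  P
}

# full matrix of P(ordered observed genotype pair) under kappa + error model
oracle_obs_matrix <- function(p, kappa, eps, mode = "freq_draw") {
  Ea <- .oracle_allele_error_matrix(p, eps, mode)
  E2 <- Ea %x% Ea   # ordered-genotype error kernel
  t(E2) %*% .oracle_true_tuple_dist(p, kappa) %*% E2
}

# P(observed unordered pair {G1}, {G2}) from an oracle_obs_matrix
oracle_lookup <- function(M, k, G1, G2) {
  G1 <- unname(as.integer(G1)); G2 <- unname(as.integer(G2))
  ords <- function(G) {
    o <- unique(list(c(G[1], G[2]), c(G[2], G[1])))
    vapply(o, function(g) (g[1] - 1L) * k + g[2], numeric(1))
  }
  sum(M[ords(G1), ords(G2), drop = FALSE])
}

# single-pair convenience wrapper (small k only)
oracle_pair_prob <- function(G1, G2, p, kappa, eps, mode = "freq_draw") {
  oracle_lookup(oracle_obs_matrix(p, kappa, eps, mode), length(p),
                as.integer(G1), as.integer(G2))
}

# kappa vectors used by the oracle, written out independently
ORACLE_KAPPA <- list(U = c(1, 0, 0), PO = c(0, 1, 0), FS = c(1/4, 1/2, 1/4),
                     HS = c(1/2, 1/2, 0), SELF = c(0, 0, 1))
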