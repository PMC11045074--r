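# Linear quantile regression by direct minimisation of the pinball (check)
# loss. Small fixed designs only (intercept + a couple of covariates), which
# is all the tail analysis here needs.

# pinball / check loss: rho_tau(u) = u * (tau - 1[u < 0])
.pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Minimise sum rho_tau(y - X b). Strategy: the intercept-only problem has
# the closed-form solution (an empirical tau-quantile); otherwise an
# iteratively reweighted least-squares pass gives a good start, Nelder-Mead
# polishes it, and a final vertex search over small active sets exploits the
# fact that an optimum interpolates p observations.
.fit_pinball <- function(X, y, tau, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  if (p == 1L) {
    return(stats::quantile(y, probs = tau, type = 1, names = FALSE) / X[1, 1])
  }
  loss <- function(b) .pinball_loss(y - drop(X %*% b), tau)

  # IRLS start (Schlossmacher-style weights with a floor)
  b <- stats::lm.fit(X, y)$coefficients
  b[is.na(b)] <- 0
  prev <- loss(b)
  for (it in seq_len(200)) {
    r <- y - drop(X %*% b)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), 1e-6)
    b_new <- tryCatch(stats::lm.wfit(X, y, w)$coefficients, error = function(e) b)
    b_new[is.na(b_new)] <- 0
    cur <- loss(b_new)
    if (cur <= prev) b <- b_new
    if (abs(prev - cur) < tol * max(1, abs(prev)) && it > 3) break
    prev <- min(prev, cur)
  }

  o <- stats::optim(b, loss, method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-14))
  if (o$value <= loss(b)) b <- o$par

  # vertex refinement: try exact interpolation through p of the
  # smallest-|residual| observations
  r <- abs(y - drop(X %*% b))
  cand <- order(r)[seq_len(min(8L, n))]
  best <- loss(b)
  for (s in utils::combn(cand, p, simplify = FALSE)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-10) next
    bs <- tryCatch(solve(Xs, y[s]), error = function(e) NULL)
    if (is.null(bs)) next
    ls <- loss(bs)
    if (ls < best - 1e-12) { best <- ls; b <- bs }
  }
  unname(b)
}
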