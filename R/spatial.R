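#' Build pair-level spatial covariates
#'
#' Joins scored pairs with both members' sampling metadata and computes the
#' covariates used by the geography-kinship analyses: the longitude
#' difference (minimal angular difference, so antimeridian crossings give
#' the short way round, always in \[0, 180\]) and \code{same_day_pos}
#' (both members sampled on the same calendar day by the same survey
#' vessel; requires both dates and vessels known). Pairs with a missing
#' coordinate are dropped with a warning. Optionally restricts to pairs
#' whose members both fall inside a longitude sector and excludes
#' field-observed mother-calf pairs (which would trivially carry a
#' sampling-proximity signal).
#'
#' @param pairs a \code{kin_pairs} data frame.
#' @param samples the [kin_samples] the pairs were scored on.
#' @param sector optional \code{c(lon_min, lon_max)} in degrees east; both
#'   members must lie inside.
#' @param exclude_field_mc drop field-observed mother-calf pairs (default
#'   TRUE).
#' @return Data frame of class \code{spatial_pairs}: \code{id_i},
#'   \code{id_j}, \code{delta_lon}, \code{same_day_pos}, \code{lod_hs},
#'   \code{lod_po}, \code{ml_category}.
#' @export
make_spatial_pairs <- function(pairs, samples, sector = NULL,
                               exclude_field_mc = TRUE) {
  stopifnot(inherits(samples, "kin_samples"))
  m <- samples$meta
  i <- match(pairs$id_i, m$sample_id)
  j <- match(pairs$id_j, m$sample_id)
  ok <- !is.na(m$lon[i]) & !is.na(m$lon[j])
  if (any(!ok)) warning(sum(!ok), " pair(s) dropped for missing coordinates")
  if (!is.null(sector)) {
    inside <- function(l) !is.na(l) & l >= sector[1] & l <= sector[2]
    ok <- ok & inside(m$lon[i]) & inside(m$lon[j])
  }
  if (exclude_field_mc) ok <- ok & !.is_field_mc(m, i, j)
  i <- i[ok]; j <- j[ok]
  out <- data.frame(
    id_i = pairs$id_i[ok], id_j = pairs$id_j[ok],
    delta_lon = delta_longitude(m$lon[i], m$lon[j]),
    same_day_pos = !is.na(m$date[i]) & !is.na(m$date[j]) &
      !is.na(m$vessel[i]) & !is.na(m$vessel[j]) &
      m$date[i] == m$date[j] & m$vessel[i] == m$vessel[j],
    lod_hs = pairs$lod_HS[ok],
    lod_po = pairs$lod_PO[ok],
    ml_category = pairs$ml_category[ok],
    stringsAsFactors = FALSE)
  class(out) <- c("spatial_pairs", "data.frame")
  out
}

#' Minimal angular longitude difference
#'
#' @param lon1,lon2 longitudes in degrees.
#' @return Difference in degrees, in \[0, 180\], taking the short way
#'   around the antimeridian.
#' @examples
#' delta_longitude(-170, 170)  # 20
#' @export
delta_longitude <- function(lon1, lon2) {
  d <- abs(lon1 - lon2) %% 360
  pmin(d, 360 - d)
}

#' Rank-sum test of longitude differences between kinship groups
#'
#' Two-sample Wilcoxon test of \code{delta_lon} between pairs
#' maximum-likelihood classified into two categories (by default PO versus
#' unrelated; HS-classified pairs are omitted because second-degree calls
#' are individually unreliable at this marker informativeness). The exact
#' null distribution is used when both groups have at most
#' \code{exact_max} pairs and there are no ties; otherwise the normal
#' approximation with tie correction. Two-sided throughout.
#'
#' @param sp a \code{spatial_pairs} data frame.
#' @param group_a,group_b maximum-likelihood category labels.
#' @param exact_max exact-enumeration size switch (per group).
#' @return List: \code{statistic} (rank-sum W of group A), \code{p_value},
#'   \code{n_a}, \code{n_b}, \code{testable}.
#' @export
wilcoxon_delta_lon <- function(sp, group_a = "PO", group_b = "U",
                               exact_max = 10) {
  xa <- sp$delta_lon[sp$ml_category == group_a]
  xb <- sp$delta_lon[sp$ml_category == group_b]
  if (!length(xa) || !length(xb))
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_a = length(xa), n_b = length(xb), testable = FALSE))
  exact <- length(xa) <= exact_max && length(xb) <= exact_max &&
    !anyDuplicated(c(xa, xb))
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(xa), n_b = length(xb), testable = TRUE)
}

#' Tail quantile regression of LOD on sampling proximity and longitude
#'
#' For each quantile level \eqn{\tau}, fits the linear \eqn{\tau}-quantile
#' of \code{lod_hs} as \eqn{b_0 + b_1 \cdot \mathrm{same\_day\_pos} + b_2
#' \cdot \Delta\mathrm{lon}} by minimising the pinball loss
#' \eqn{\sum_i \rho_\tau(y_i - x_i'b)}, \eqn{\rho_\tau(u) = u(\tau -
#' 1[u<0])}. Close kin live in the far right tail of the LOD distribution,
#' so the interesting \eqn{\tau} are near 1: a positive \eqn{b_1}
#' concentrated around the tail mass contributed by second-degree kin
#' indicates excess relatedness among pairs sampled together; a negative
#' \eqn{b_2} would indicate geographical aggregation of kin. 95%
#' confidence bands are pair-level bootstrap percentiles (resampling rows,
#' seeded).
#'
#' @param sp a \code{spatial_pairs} data frame (>= 10 rows).
#' @param taus quantile levels in (0, 1).
#' @param n_boot bootstrap resamples for the confidence bands.
#' @param seed RNG seed for the bootstrap.
#' @param level confidence level of the bands.
#' @return Data frame of class \code{kin_rq}: \code{tau}, \code{term}
#'   (\code{b0}, \code{b1_same_day_pos}, \code{b2_delta_lon}),
#'   \code{estimate}, \code{lower}, \code{upper}; attribute \code{"n"}.
#'   With a degenerate design (no variation in either covariate) an
#'   intercept-only fit is returned with a warning, \code{b0} then equals
#'   the empirical \eqn{\tau}-quantile.
#' @export
quantile_regression <- function(sp, taus = seq(0.90, 0.99, by = 0.01),
                                n_boot = 200, seed = 1, level = 0.95) {
  if (nrow(sp) < 10) stop("need at least 10 pairs for quantile regression")
  if (any(taus <= 0 | taus >= 1)) stop("taus must be in (0, 1)")
  y <- sp$lod_hs
  sdp <- as.numeric(sp$same_day_pos)
  dlon <- sp$delta_lon
  keep_sdp <- stats::var(sdp) > 0
  keep_dlon <- stats::var(dlon) > 0
  if (!keep_sdp && !keep_dlon) {
    warning("degenerate design: no variation in covariates; intercept-only fit")
    X <- cbind(b0 = rep(1, length(y)))
  } else {
    X <- cbind(b0 = 1,
               if (keep_sdp) sdp else NULL,
               if (keep_dlon) dlon else NULL)
    colnames(X) <- c("b0", if (keep_sdp) "b1_same_day_pos",
                     if (keep_dlon) "b2_delta_lon")
  }
  p <- ncol(X)
  fit_all <- function(Xm, ym) matrix(
    vapply(taus, function(tau) .fit_pinball(Xm, ym, tau),
           numeric(ncol(Xm))),
    nrow = ncol(Xm))
  est <- fit_all(X, y)             # p x n_taus
  set.seed(seed)
  n <- length(y)
  boots <- array(NA_real_, c(p, length(taus), n_boot))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    # a bootstrap sample can lose covariate variation; refit what it supports
    ok_cols <- c(TRUE, apply(Xb[, -1, drop = FALSE], 2,
                             function(cl) stats::var(cl) > 0))
    cf <- fit_all(Xb[, ok_cols, drop = FALSE], y[idx])
    boots[ok_cols, , b] <- cf
  }
  alpha <- (1 - level) / 2
  out <- do.call(rbind, lapply(seq_along(taus), function(ti) {
    data.frame(tau = taus[ti], term = colnames(X),
               estimate = est[, ti],
               lower = apply(boots[, ti, , drop = FALSE], 1, stats::quantile,
                             probs = alpha, na.rm = TRUE),
               upper = apply(boots[, ti, , drop = FALSE], 1, stats::quantile,
                             probs = 1 - alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n") <- n
  class(out) <- c("kin_rq", "data.frame")
  out
}

#' Compare LOD distributions between sampling-proximity strata
#'
#' Empirical cumulative distribution functions of \code{lod_hs} for pairs
#' with and without \code{same_day_pos}, with an optional reference LOD
#' (typically the median of the simulated half-sibling LOD distribution):
#' excess upper-tail mass in the same-day stratum around that reference is
#' the distributional signature of second-degree kin among pairs sampled
#' together.
#'
#' @param sp a \code{spatial_pairs} data frame.
#' @param ref_lod optional reference LOD value.
#' @return List: \code{ecdf_same_day}, \code{ecdf_other} (functions, or
#'   \code{NULL} for an empty stratum, with a warning), \code{ref_lod},
#'   \code{n_same_day}, \code{n_other}.
#' @export
ecdf_compare <- function(sp, ref_lod = NULL) {
  a <- sp$lod_hs[sp$same_day_pos]
  b <- sp$lod_hs[!sp$same_day_pos]
  if (!length(a) || !length(b)) warning("one sampling-proximity stratum is empty")
  list(ecdf_same_day = if (length(a)) stats::ecdf(a) else NULL,
       ecdf_other = if (length(b)) stats::ecdf(b) else NULL,
       ref_lod = ref_lod, n_same_day = length(a), n_other = length(b))
}
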