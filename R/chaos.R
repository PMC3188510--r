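# Nonlinear time-series analysis of LFP-like signals: delay embedding,
# false-nearest-neighbor dimension diagnostics, neighbor-divergence curves
# and largest-Lyapunov-exponent extraction.

#' Delay embedding of a scalar series
#'
#' Builds the lagged vectors
#' `s_n = (x_n, x_{n-tau}, ..., x_{n-(m-1) tau})`; the number of vectors is
#' `length(x) - (m - 1) tau`.
#'
#' @param x numeric vector or [signal_series()].
#' @param m embedding dimension (>= 1).
#' @param tau reconstruction delay, samples (>= 1).
#' @return an `embedding_set`: matrix (vectors x m) with attributes `m`,
#'   `tau`.
#' @export
delay_embed <- function(x, m, tau) {
  x <- .as_samples(x)
  stopifnot(m >= 1, tau >= 1)
  L <- length(x) - (m - 1) * tau
  if (L < 1) stop("series too short for this embedding", call. = FALSE)
  emb <- vapply(seq_len(m), function(k) x[(1:L) + (m - k) * tau],
                numeric(L))
  emb <- matrix(emb, nrow = L, ncol = m)
  structure(emb, m = m, tau = tau, class = c("embedding_set", "matrix"))
}

#' First zero crossing of the autocorrelation
#'
#' Default heuristic for the reconstruction delay: the first lag at which
#' the autocorrelation of the series crosses zero.
#'
#' @param x numeric vector or [signal_series()].
#' @param max_lag maximal searched lag, samples.
#' @return lag in samples (max_lag if no crossing is found).
#' @export
first_zero_autocorr <- function(x, max_lag = 1000) {
  x <- .as_samples(x)
  x <- x - mean(x)
  n <- length(x)
  max_lag <- min(max_lag, n - 2)
  for (l in seq_len(max_lag)) {
    if (sum(x[1:(n - l)] * x[(1 + l):n]) <= 0) return(l)
  }
  max_lag
}

#' Fraction of false nearest neighbors per embedding dimension
#'
#' For each dimension `m`, finds the nearest neighbor of a sample of
#' reference vectors (excluding temporally close pairs within the Theiler
#' window) and flags the pair as false when the extra coordinate of the
#' `m + 1` embedding inflates their distance by more than `r_star`, or when
#' the inflated distance is no longer small relative to the attractor size
#' (`a_tol` times the series SD) - the standard two-part criterion, which
#' keeps stochastic signals at high false fractions at every dimension.
#' Deterministic signals yield fractions that drop toward zero at the
#' attractor's embedding dimension.
#'
#' @param x numeric vector or [signal_series()].
#' @param tau reconstruction delay, samples.
#' @param m_range embedding dimensions tested.
#' @param r_star distance-ratio threshold.
#' @param a_tol attractor-size threshold, in units of the series SD.
#' @param n_ref number of reference points sampled.
#' @param theiler temporal exclusion window, samples.
#' @return data.frame with `m` and `fraction`.
#' @export
false_nearest_neighbors <- function(x, tau, m_range = 1:6, r_star = 10,
                                    a_tol = 1, n_ref = 400, theiler = NULL) {
  x <- .as_samples(x)
  sd_x <- sd(x)
  if (is.null(theiler)) theiler <- tau
  frac <- vapply(m_range, function(m) {
    emb <- delay_embed(x, m, tau)
    emb1 <- delay_embed(x, m + 1, tau)
    L <- nrow(emb1)                 # usable vectors in both embeddings
    if (L < 10 * theiler) stop("not enough candidate pairs", call. = FALSE)
    refs <- unique(round(seq(1, L, length.out = min(n_ref, L))))
    false <- 0; total <- 0
    for (i in refs) {
      d2 <- rowSums((emb[1:L, , drop = FALSE] -
                       matrix(emb[i, ], L, m, byrow = TRUE))^2)
      d2[abs(seq_len(L) - i) <= theiler] <- Inf
      j <- which.min(d2)
      if (!is.finite(d2[j]) || d2[j] == 0) next
      dist_m <- sqrt(d2[j])
      # the added coordinate of the m+1 embedding is the forward extension
      extra <- abs(emb1[i, 1] - emb1[j, 1])
      total <- total + 1
      if (extra / dist_m > r_star ||
          sqrt(dist_m^2 + extra^2) > a_tol * sd_x) false <- false + 1
    }
    if (total == 0) stop("not enough candidate pairs", call. = FALSE)
    false / total
  }, numeric(1))
  data.frame(m = m_range, fraction = frac)
}

#' Neighbor-divergence curve
#'
#' For reference points whose delay-embedding neighborhoods (radius `eps`,
#' Theiler-excluded) are non-empty, follows the neighborhoods forward and
#' records `S(dn) = <ln(mean distance after dn steps)>` over reference
#' points.  A sustained linear increase of `S` marks exponential
#' separation; its slope estimates the largest Lyapunov exponent.
#'
#' @param embedding an [delay_embed()] result.
#' @param eps neighborhood radius (same units as the series).
#' @param horizon maximal look-ahead, samples.
#' @param min_pairs minimal total neighbor pairs required.
#' @param theiler temporal exclusion window, samples.
#' @param n_ref maximal number of reference points examined.
#' @return a `divergence_curve`: list with `dn`, `s` (natural log), `eps`,
#'   `n_pairs`, `m`.
#' @export
divergence_curve <- function(embedding, eps, horizon = 50,
                             min_pairs = 1000, theiler = NULL,
                             n_ref = 2000) {
  emb <- unclass(embedding)
  m <- attr(embedding, "m"); tau <- attr(embedding, "tau")
  if (is.null(theiler)) theiler <- max(tau, 1)
  L <- nrow(emb)
  usable <- L - horizon
  if (usable < 10) stop("series too short for the horizon", call. = FALSE)
  refs <- unique(round(seq(1, usable, length.out = min(n_ref, usable))))
  s_acc <- matrix(NA_real_, length(refs), horizon + 1)
  n_pairs <- 0
  kept <- 0
  for (r in seq_along(refs)) {
    i <- refs[r]
    d2 <- rowSums((emb[1:usable, , drop = FALSE] -
                     matrix(emb[i, ], usable, m, byrow = TRUE))^2)
    d2[abs(seq_len(usable) - i) <= theiler] <- Inf
    nb <- which(d2 <= eps^2)
    if (length(nb) == 0) next
    kept <- kept + 1
    n_pairs <- n_pairs + length(nb)
    for (dn in 0:horizon) {
      d <- sqrt(rowSums((emb[nb + dn, , drop = FALSE] -
                           matrix(emb[i + dn, ], length(nb), m,
                                  byrow = TRUE))^2))
      s_acc[kept, dn + 1] <- log(pmax(mean(d), 1e-300))
    }
  }
  if (kept == 0 || n_pairs < min_pairs)
    stop(sprintf("only %d neighbor pairs found (need %d); increase eps",
                 n_pairs, min_pairs), call. = FALSE)
  structure(list(dn = 0:horizon,
                 s = colMeans(s_acc[seq_len(kept), , drop = FALSE]),
                 eps = eps, n_pairs = n_pairs, m = m, tau = tau),
            class = "divergence_curve")
}

#' Largest-Lyapunov-exponent estimate from divergence curves
#'
#' Scans the divergence curves of several embedding dimensions for a
#' common linear scaling region: a window of at least `min_window` points
#' (dn > 0) in which every local slope stays within `slope_tol` of the
#' window mean, the curve rises by at least `min_gain` (natural log), and
#' the per-dimension window slopes agree within `slope_tol`.  Returns the
#' mean slope converted to 1/ms, or a "no linear scaling region" verdict.
#'
#' @param curves list of `divergence_curve` (>= 2 embedding dimensions).
#' @param dt_ms sampling interval underlying one `dn` step, ms (1 for
#'   map-time units).
#' @param min_window minimal window length, points.
#' @param slope_tol relative slope tolerance.
#' @param min_gain minimal total rise of S across the window, nats.
#' @return list with `lambda_max` (1/ms, NA when no region), `chaotic`,
#'   `verdict`, `window`, `slopes` (per curve).
#' @export
estimate_lambda_max <- function(curves, dt_ms = 1, min_window = 4,
                                slope_tol = 0.2, min_gain = 0.4) {
  stopifnot(length(curves) >= 2)
  window_slope <- function(cv, i0, i1) {
    sel <- i0:i1
    unname(coef(stats::lm(cv$s[sel + 1] ~ cv$dn[sel + 1]))[2])
  }
  best <- NULL
  horizon <- min(vapply(curves, function(cv) max(cv$dn), numeric(1)))
  for (i0 in 1:(horizon - min_window)) {
    for (i1 in (i0 + min_window):horizon) {
      ok <- TRUE
      slopes <- numeric(length(curves))
      for (k in seq_along(curves)) {
        cv <- curves[[k]]
        sel <- (i0:i1) + 1
        loc <- diff(cv$s[sel]) / diff(cv$dn[sel])
        mslope <- mean(loc)
        if (mslope <= 0 ||
            any(abs(loc - mslope) > slope_tol * abs(mslope)) ||
            (cv$s[max(sel)] - cv$s[min(sel)]) < min_gain) {
          ok <- FALSE
          break
        }
        slopes[k] <- mslope
      }
      if (!ok) next
      ms <- mean(slopes)
      if (any(abs(slopes - ms) > slope_tol * abs(ms))) next
      if (is.null(best) || (i1 - i0) > (best$i1 - best$i0))
        best <- list(i0 = i0, i1 = i1, slopes = slopes)
    }
  }
  if (is.null(best)) {
    return(list(lambda_max = NA_real_, chaotic = FALSE,
                verdict = "no linear scaling region",
                window = NULL, slopes = NULL))
  }
  list(lambda_max = mean(best$slopes) / dt_ms, chaotic = TRUE,
       verdict = "chaotic: linear scaling region found",
       window = c(best$i0, best$i1), slopes = best$slopes)
}

#' Phase-randomized surrogate
#'
#' Randomizes the Fourier phases of a series while preserving its power
#' spectrum; destroys deterministic structure, so a chaotic verdict should
#' flip on the surrogate.
#'
#' @param x numeric vector or [signal_series()].
#' @return numeric surrogate series.
#' @export
phase_randomize <- function(x) {
  x <- .as_samples(x)
  n <- length(x)
  X <- fft(x)
  half <- floor((n - 1) / 2)
  ph <- runif(half, 0, 2 * pi)
  X[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * ph)
  X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
  Re(fft(X, inverse = TRUE)) / n
}

#' Logistic-map series
#'
#' Iterates `x -> r x (1 - x)`; at r = 4 the map is chaotic with
#' `lambda = ln 2` per iteration, the standard oracle for the divergence
#' pipeline.
#'
#' @param n length.
#' @param r map parameter.
#' @param x0 initial value.
#' @param burn discarded transient iterations.
#' @return numeric vector.
#' @export
logistic_map_series <- function(n, r = 4, x0 = 0.2, burn = 100) {
  x <- x0
  for (k in seq_len(burn)) x <- r * x * (1 - x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    x <- r * x * (1 - x)
    out[k] <- x
  }
  out
}

#' End-to-end chaos analysis of a series
#'
#' Delay selection (first autocorrelation zero unless given), embeddings
#' over `m_range`, divergence curves and the lambda estimate.
#'
#' @param x numeric vector or [signal_series()].
#' @param m_range embedding dimensions.
#' @param tau delay, samples (`NULL`: first autocorrelation zero).
#' @param eps neighborhood radius (`NULL`: 1/20 of the series SD-scaled
#'   range, grown until `min_pairs` is met).
#' @param horizon look-ahead, samples.
#' @param min_pairs minimal neighbor pairs per curve.
#' @param dt_ms sample interval, ms.
#' @return list with `tau`, `eps`, `curves`, `estimate`, `fnn` (NULL unless
#'   `fnn = TRUE`).
#' @export
chaos_analysis <- function(x, m_range = 3:5, tau = NULL, eps = NULL,
                           horizon = 50, min_pairs = 1000, dt_ms = 1,
                           fnn = FALSE) {
  xs <- .as_samples(x)
  if (is.null(tau)) tau <- first_zero_autocorr(xs)
  if (is.null(eps)) eps <- 0.05 * sd(xs)
  curves <- lapply(m_range, function(m) {
    emb <- delay_embed(xs, m, tau)
    e <- eps
    repeat {
      cv <- tryCatch(divergence_curve(emb, e, horizon, min_pairs,
                                      theiler = tau),
                     error = function(err) NULL)
      if (!is.null(cv)) return(cv)
      e <- e * 1.5
      if (e > 100 * sd(xs)) stop("no usable neighborhoods", call. = FALSE)
    }
  })
  est <- estimate_lambda_max(curves, dt_ms = dt_ms)
  list(tau = tau, eps = eps, curves = curves, estimate = est,
       fnn = if (fnn) false_nearest_neighbors(xs, tau,
                                              m_range = m_range) else NULL)
}
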