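#' Two-component Gaussian mixture threshold for 1-D intensities
#'
#' Fits a two-component Gaussian mixture by EM, initialised from the
#' 25th/75th-percentile split, and returns the threshold at the intersection
#' of the two weighted component densities between the means, i.e. the root
#' of \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)} on
#' \eqn{(\mu_1, \mu_2)}. If the densities do not cross between the means
#' (degenerate overlap) the midpoint is used with a warning.
#'
#' @param x numeric intensities (>= 100 events).
#' @param seed integer seed (EM is deterministic given the quantile
#'   initialisation; the seed only guards optional restarts).
#' @param maxIter,tol EM controls.
#' @return list: mu (sorted), sigma, weight, threshold, loglik, converged.
#' @export
gmmThreshold <- function(x, seed = 1, maxIter = 500, tol = 1e-8) {
  if (length(x) < 100) stop("need >= 100 events")
  q <- quantile(x, c(0.25, 0.75))
  lower <- x <= median(x)
  mu <- c(q[[1]], q[[2]])
  s <- rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(mean(lower), 1 - mean(lower))
  ll <- -Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    newll <- sum(log(tot))
    w <- c(mean(g), 1 - mean(g))
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    s <- sqrt(c(sum(g * (x - mu[1])^2) / sum(g),
                sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    s <- pmax(s, 1e-9)
    if (is.finite(ll) && abs(newll - ll) < tol * (1 + abs(ll))) {
      converged <- TRUE; ll <- newll; break
    }
    ll <- newll
  }
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; w <- w[ord]
  f <- function(t) w[1] * dnorm(t, mu[1], s[1]) - w[2] * dnorm(t, mu[2], s[2])
  eps <- (mu[2] - mu[1]) * 1e-9
  threshold <- if (mu[2] - mu[1] < 1e-12 ||
                   sign(f(mu[1] + eps)) == sign(f(mu[2] - eps))) {
    warning("no density crossing between the means; using the midpoint")
    mean(mu)
  } else uniroot(f, c(mu[1] + eps, mu[2] - eps), tol = 1e-12)$root
  list(mu = mu, sigma = s, weight = w, threshold = threshold,
       loglik = ll, converged = converged)
}

#' Classify two-channel flow-cytometry events and report signal frequency
#'
#' Thresholds each channel with [gmmThreshold()], discards double-negative
#' and double-positive (doublet) events, and reports the fraction of
#' retained events without signal in the mCherry channel.
#'
#' @param gfp,mcherry per-event intensities (equal lengths).
#' @param seed integer seed.
#' @return list: thresholds, counts (signal / no-signal / discarded),
#'   frequency (proportion of retained events without mCherry signal).
#' @export
competitionFrequency <- function(gfp, mcherry, seed = 1) {
  stopifnot(length(gfp) == length(mcherry))
  tg <- gmmThreshold(gfp, seed = seed)
  tm <- gmmThreshold(mcherry, seed = seed)
  gPos <- gfp > tg$threshold
  mPos <- mcherry > tm$threshold
  keep <- xor(gPos, mPos)  # drop double-negatives and doublets
  list(thresholds = c(gfp = tg$threshold, mcherry = tm$threshold),
       counts = c(retained = sum(keep),
                  double_negative = sum(!gPos & !mPos),
                  doublets = sum(gPos & mPos)),
       frequency = if (any(keep)) mean(!mPos[keep]) else NA_real_)
}
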