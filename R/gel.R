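# Gel densitometry: moving-median background, band quantification, and
# Bayesian credible intervals for replicate efficiencies.

#' LaneProfile: a 1-D gel lane intensity profile
#'
#' @slot positions Pixel positions, strictly increasing.
#' @slot intensities Intensities (arbitrary units), same length, finite.
#' @exportClass LaneProfile
setClass("LaneProfile",
  representation(positions = "numeric", intensities = "numeric"))

setValidity("LaneProfile", function(object) {
  msgs <- character()
  if (length(object@positions) != length(object@intensities))
    msgs <- c(msgs, "'positions' and 'intensities' must have equal length")
  if (length(object@positions) < 3L)
    msgs <- c(msgs, "a lane profile needs at least 3 samples")
  if (any(diff(object@positions) <= 0))
    msgs <- c(msgs, "'positions' must be strictly increasing")
  if (!all(is.finite(object@intensities)))
    msgs <- c(msgs, "'intensities' must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @param positions,intensities Numeric vectors (px, a.u.).
#' @rdname LaneProfile-class
#' @export
LaneProfile <- function(positions, intensities) {
  new("LaneProfile", positions = as.numeric(positions),
      intensities = as.numeric(intensities))
}

#' @export
setMethod("length", "LaneProfile", function(x) length(x@positions))

#' @export
setMethod("show", "LaneProfile", function(object) {
  cat(sprintf("LaneProfile: %d samples over [%g, %g] px\n",
              length(object@positions), min(object@positions),
              max(object@positions)))
})

#' @rdname LaneProfile-class
#' @param x,object A `LaneProfile`.
#' @export
lanePositions <- function(x) x@positions

#' @rdname LaneProfile-class
#' @export
laneIntensities <- function(x) x@intensities

#' Read a lane profile from a two-column CSV
#'
#' Expects columns `position_px, intensity` (header row optional).
#'
#' @param path CSV file path.
#' @return A [LaneProfile-class].
#' @export
readLaneProfile <- function(path) {
  if (!file.exists(path)) .stopf("profile file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*-?[0-9.]", first)
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L) .stopf("'%s' must have two columns", path)
  LaneProfile(df[[1L]], df[[2L]])
}

#' ReplicateSet: replicate efficiency measurements
#'
#' @slot values The replicate measurements.
#' @exportClass ReplicateSet
setClass("ReplicateSet", representation(values = "numeric"))

setValidity("ReplicateSet", function(object) {
  if (length(object@values) < 2L) return("at least 2 replicates are required")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' @param values Numeric vector of replicate measurements (n >= 2).
#' @rdname ReplicateSet-class
#' @export
ReplicateSet <- function(values) new("ReplicateSet", values = as.numeric(values))

#' @export
setMethod("length", "ReplicateSet", function(x) length(x@values))

#' @rdname ReplicateSet-class
#' @param x A `ReplicateSet`.
#' @export
replicateValues <- function(x) x@values

#' CredibleInterval: an equal-tailed Bayesian credible interval
#'
#' @slot level Credibility level in (0, 1).
#' @slot lo,hi Interval endpoints.
#' @slot posterior_mean,posterior_sd Posterior moments of the mean.
#' @slot replicate_sd Plain sample standard deviation of the replicates,
#'   reported alongside the posterior sd because summaries quoted as
#'   "x +/- y" may refer to either.
#' @exportClass CredibleInterval
setClass("CredibleInterval",
  representation(level = "numeric", lo = "numeric", hi = "numeric",
                 posterior_mean = "numeric", posterior_sd = "numeric",
                 replicate_sd = "numeric"))

setValidity("CredibleInterval", function(object) {
  if (object@level <= 0 || object@level >= 1) return("'level' must be in (0,1)")
  tol <- 1e-8 * max(1, abs(object@hi - object@lo))
  if (object@lo > object@hi + tol) return("'lo' must not exceed 'hi'")
  TRUE
})

#' @export
setMethod("show", "CredibleInterval", function(object) {
  cat(sprintf("%.0f%% credible interval: [%.4g, %.4g]\n", 100 * object@level,
              object@lo, object@hi))
  cat(sprintf("  posterior mean %.4g (posterior sd %.3g, replicate sd %.3g)\n",
              object@posterior_mean, object@posterior_sd, object@replicate_sd))
})

#' @rdname CredibleInterval-class
#' @param x A `CredibleInterval`.
#' @export
ciBounds <- function(x) c(lo = x@lo, hi = x@hi)

#' @rdname CredibleInterval-class
#' @export
posteriorMean <- function(x) x@posterior_mean

#' Moving-median background estimation for a lane profile
#'
#' Element-wise running median over a centered window with reflected edges,
#' the background model used for all gel quantifications here. The median is
#' insensitive to sharp bands riding on a smooth drifting background.
#'
#' @param profile A [LaneProfile-class].
#' @param windowPx Window size in samples (odd; even values are rounded up
#'   to the next odd with a notice). Must satisfy
#'   `3 <= windowPx <= length(profile)`.
#' @return Numeric background vector, same length as the profile.
#' @export
movingMedianBackground <- function(profile, windowPx) {
  stopifnot(is(profile, "LaneProfile"))
  n <- length(profile)
  windowPx <- as.integer(windowPx)
  if (windowPx > n) .stopf("'windowPx' (%d) exceeds profile length (%d)",
                           windowPx, n)
  if (windowPx < 3L) .stopf("'windowPx' must be >= 3")
  if (windowPx %% 2L == 0L) {
    windowPx <- windowPx + 1L
    message(sprintf("even window rounded up to %d", windowPx))
    if (windowPx > n) windowPx <- windowPx - 2L
  }
  k <- (windowPx - 1L) %/% 2L
  y <- profile@intensities
  pad <- c(rev(y[seq(2L, k + 1L)]), y, rev(y[seq(n - k, n - 1L)]))
  bg <- stats::runmed(pad, windowPx, endrule = "keep")
  as.numeric(bg[(k + 1L):(k + n)])
}

.check_band_windows <- function(windows, profile) {
  req <- c("label", "start_px", "end_px")
  if (!is.data.frame(windows) || !all(req %in% names(windows)) ||
      nrow(windows) < 1L)
    .stopf("'windows' must be a data.frame with columns %s",
           paste(req, collapse = ", "))
  if (any(windows$start_px >= windows$end_px))
    .stopf("each band window needs start_px < end_px")
  rng <- range(profile@positions)
  if (any(windows$start_px < rng[1L] | windows$end_px > rng[2L]))
    .stopf("band windows must lie inside the profile range [%g, %g]",
           rng[1L], rng[2L])
  o <- order(windows$start_px)
  s <- windows$start_px[o]; e <- windows$end_px[o]
  if (any(s[-1L] < e[-length(e)]))
    .stopf("band windows may not overlap")
  invisible(windows)
}

#' Quantify gel bands as background-subtracted fractions
#'
#' Subtracts the moving-median background, clamps the residual signal at 0,
#' integrates it (trapezoidal rule) over each band window and normalises the
#' band areas to fractions.
#'
#' @param profile A [LaneProfile-class].
#' @param windows `data.frame` with columns `label`, `start_px`, `end_px`;
#'   windows may not overlap.
#' @param windowPx Moving-median window in samples; defaults to 3x the
#'   widest declared band window.
#' @return `data.frame` with columns `label`, `area`, `fraction`
#'   (fractions sum to 1).
#' @export
quantifyBands <- function(profile, windows, windowPx = NULL) {
  stopifnot(is(profile, "LaneProfile"))
  .check_band_windows(windows, profile)
  x <- profile@positions
  if (is.null(windowPx)) {
    spacing <- median(diff(x))
    widest <- max(windows$end_px - windows$start_px)
    windowPx <- round(3 * widest / spacing)
  }
  windowPx <- max(3L, min(length(profile), as.integer(windowPx)))
  bg <- movingMedianBackground(profile, windowPx)
  sig <- pmax(profile@intensities - bg, 0)
  areas <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- x >= windows$start_px[i] & x <= windows$end_px[i]
    .trapz(x[sel], sig[sel])
  }, numeric(1))
  if (sum(areas) <= 0) .stopf("empty lane: no signal above background")
  data.frame(label = windows$label, area = areas,
             fraction = areas / sum(areas), stringsAsFactors = FALSE)
}

# Shared posterior engine. Joint posterior on the (mu, sigma) box:
#   p(mu, sigma | x) propto sigma^-n exp(-S(mu)/(2 sigma^2)) * sigma^-2
# with S(mu) = sum (x_i - mu)^2, integrated over sigma on a log-spaced grid
# (method "grid") or in closed form S(mu)^-((n+1)/2) (method "analytic").
.posterior_mu <- function(values, level, mu_prior, n_mu = 1001L,
                          n_sigma = 400L, sigma_range = NULL,
                          method = c("grid", "analytic"),
                          allow_zero_var = FALSE) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 2L) .stopf("at least 2 replicates are required")
  if (mu_prior[1L] >= mu_prior[2L]) .stopf("invalid mu prior interval")
  rng <- diff(range(values))
  if (rng == 0 && !allow_zero_var)
    .stopf(paste("zero sample variance: the posterior degenerates;",
                 "use a wider sigma grid floor (sigma_range) if intended"))
  if (is.null(sigma_range)) {
    if (rng == 0) sigma_range <- c(1e-6, 1)
    else sigma_range <- c(1e-4 * rng, 10 * rng)
  }
  mu <- seq(mu_prior[1L], mu_prior[2L], length.out = n_mu)
  sumx <- sum(values); sumx2 <- sum(values^2)
  S <- sumx2 - 2 * mu * sumx + n * mu^2
  S <- pmax(S, .Machine$double.xmin)
  if (method == "analytic") {
    logp <- -(n + 1) / 2 * log(S)
  } else {
    lsig <- seq(log(sigma_range[1L]), log(sigma_range[2L]),
                length.out = n_sigma)
    sig2 <- exp(2 * lsig)
    # integrate over log sigma: d sigma = sigma d(log sigma), so the
    # sigma^-(n+2) density picks up one power of sigma
    w <- c(diff(lsig)[1L] / 2,
           (diff(lsig)[-1L] + diff(lsig)[-(n_sigma - 1L)]) / 2,
           diff(lsig)[n_sigma - 1L] / 2)
    expo <- outer(-S / 2, 1 / sig2) + matrix(rep(-(n + 1) * lsig, each = n_mu),
                                             nrow = n_mu)
    m <- max(expo)
    logp <- log(as.numeric(exp(expo - m) %*% w)) + m
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  z <- .trapz(mu, p)
  p <- p / z
  cdf <- cumsum(c(0, diff(mu) * (p[-1L] + p[-n_mu]) / 2))
  cdf <- cdf / cdf[n_mu]
  qtl <- function(q) {
    i <- findInterval(q, cdf, all.inside = TRUE)
    x0 <- mu[i]; x1 <- mu[i + 1L]; c0 <- cdf[i]; c1 <- cdf[i + 1L]
    if (c1 == c0) x0 else x0 + (q - c0) / (c1 - c0) * (x1 - x0)
  }
  a <- (1 - level) / 2
  pm <- .trapz(mu, mu * p)
  psd <- sqrt(max(.trapz(mu, (mu - pm)^2 * p), 0))
  new("CredibleInterval", level = level, lo = qtl(a), hi = qtl(1 - a),
      posterior_mean = pm, posterior_sd = psd,
      replicate_sd = stats::sd(values))
}

#' Bayesian credible interval for a mean efficiency
#'
#' Posterior for the mean of replicate measurements under a normal
#' likelihood with unknown `sigma`, a uniform prior for the mean on
#' `muPrior` (default `[0, 1]`, the efficiency scale) and a
#' \eqn{1/\sigma^2} prior for `sigma`, truncated to a log-spaced grid for
#' propriety. `sigma` is marginalised numerically (default) or analytically
#' (the closed-form marginal \eqn{S(\mu)^{-(n+1)/2}}); the returned interval
#' is equal-tailed.
#'
#' @param data A [ReplicateSet-class] or numeric vector (n >= 2, non-zero
#'   sample variance).
#' @param level Credibility level (default 0.95).
#' @param muPrior Length-2 prior interval for the mean.
#' @param nMuGrid,nSigmaGrid Grid sizes (>= 200 recommended).
#' @param sigmaRange Optional `c(sigma_min, sigma_max)`; defaults to
#'   `c(1e-4, 10) * range(data)`.
#' @param method `"grid"` (numeric sigma marginalisation, default) or
#'   `"analytic"` (closed-form sigma marginal).
#' @return A [CredibleInterval-class].
#' @examples
#' posteriorMuCI(c(0.20, 0.22, 0.24))
#' @export
posteriorMuCI <- function(data, level = 0.95, muPrior = c(0, 1),
                          nMuGrid = 1001L, nSigmaGrid = 400L,
                          sigmaRange = NULL, method = c("grid", "analytic")) {
  values <- if (is(data, "ReplicateSet")) data@values else as.numeric(data)
  .posterior_mu(values, level, muPrior, nMuGrid, nSigmaGrid, sigmaRange,
                method)
}

#' Credible interval for signal relative to a reference condition
#'
#' For chromosome entrapment assays: per-replicate ratios
#' `sample_i / mean(reference)` form the data; the mean gets a uniform prior
#' on `[-10 xbar, +10 xbar]` (xbar = sample mean of the ratios, so the prior
#' permits negative values) and sigma the \eqn{1/\sigma^2} prior. When the
#' ratios are identically zero the data-dependent prior collapses, so a
#' fixed half-width of 1 and an absolute sigma floor are used instead.
#'
#' @param sample,reference [ReplicateSet-class] objects (or numeric
#'   vectors); `mean(reference)` must be positive.
#' @param level Credibility level (default 0.95).
#' @param ... Passed to the posterior engine (grid sizes, method).
#' @return A [CredibleInterval-class] on the ratio scale.
#' @export
relativeSignalCI <- function(sample, reference, level = 0.95, ...) {
  s <- if (is(sample, "ReplicateSet")) sample@values else as.numeric(sample)
  r <- if (is(reference, "ReplicateSet")) reference@values else as.numeric(reference)
  if (length(s) < 2L) .stopf("at least 2 sample replicates are required")
  if (mean(r) <= 0) .stopf("reference mean must be positive")
  ratios <- s / mean(r)
  xbar <- mean(ratios)
  h <- 10 * abs(xbar)
  if (h == 0) h <- 1 # degenerate all-zero sample
  .posterior_mu(ratios, level, c(-h, h), allow_zero_var = TRUE, ...)
}
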