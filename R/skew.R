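#' SkewProfile: cumulative GC skew with ori/ter calls
#'
#' Windowed GC skew \eqn{(n_G - n_C)/(n_G + n_C)} and its running sum along a
#' genome. On circular bacterial chromosomes the cumulative curve attains its
#' global maximum at the replication terminus and its global minimum at the
#' origin (leading-strand G bias convention). Calls are reported at the
#' boundary (end coordinate) of the extremal window, 0-based.
#'
#' @slot window,step Window and step sizes in bp.
#' @slot starts 0-based window start coordinates.
#' @slot skew Per-window skew values.
#' @slot cumulative Running sum of `skew`.
#' @slot ori_pos,ter_pos 0-based calls (`NA` when the profile is flat).
#' @slot genome_length,circular Genome context.
#' @exportClass SkewProfile
setClass("SkewProfile",
  representation(window = "integer", step = "integer", starts = "numeric",
                 skew = "numeric", cumulative = "numeric",
                 ori_pos = "numeric", ter_pos = "numeric",
                 genome_length = "numeric", circular = "logical"))

setValidity("SkewProfile", function(object) {
  if (length(object@skew) != length(object@cumulative))
    return("'skew' and 'cumulative' must have equal length")
  if (length(object@skew) != length(object@starts))
    return("one cumulative entry per window is required")
  TRUE
})

#' @export
setMethod("show", "SkewProfile", function(object) {
  cat(sprintf("SkewProfile: %d windows of %d bp (step %d) over %g bp\n",
              length(object@skew), object@window, object@step,
              object@genome_length))
  if (is.na(object@ter_pos)) {
    cat("  flat profile: ori/ter undefined\n")
  } else {
    cat(sprintf("  ori = %g, ter = %g (0-based)\n", object@ori_pos,
                object@ter_pos))
  }
})

#' @rdname SkewProfile-class
#' @param x A `SkewProfile`.
#' @export
terPos <- function(x) x@ter_pos

#' @rdname SkewProfile-class
#' @export
oriPos <- function(x) x@ori_pos

#' @rdname SkewProfile-class
#' @export
skewCumulative <- function(x) x@cumulative

#' Cumulative GC skew and replication ori/ter prediction
#'
#' Computes per-window skew `(nG - nC)/(nG + nC)` (0 for G+C-free windows),
#' its running sum starting from 0, and calls the replication terminus at
#' the global maximum of the cumulative curve and the origin at the global
#' minimum. Ties are broken towards the smallest genomic coordinate. For a
#' flat (all-zero skew) profile both calls are `NA`.
#'
#' @param genome A [CircularGenome-class].
#' @param window Window size in bp (default 1000; must not exceed the genome).
#' @param step Step size in bp, `1 <= step <= window` (default `window`,
#'   i.e. non-overlapping windows).
#' @return A [SkewProfile-class].
#' @examples
#' g <- CircularGenome("toy", "GGGGGCCCCC", circular = TRUE)
#' p <- cumulativeGCSkew(g, window = 1, step = 1)
#' terPos(p) # 5
#' oriPos(p) # 0
#' @export
cumulativeGCSkew <- function(genome, window = 1000L, step = window) {
  stopifnot(is(genome, "CircularGenome"))
  L <- length(genome)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || window > L)
    .stopf("'window' must satisfy 1 <= window <= genome length (%d)", L)
  if (step < 1L || step > window)
    .stopf("'step' must satisfy 1 <= step <= window")

  seqc <- strsplit(as.character(genome@seq), "")[[1]]
  gcum <- cumsum(seqc == "G")
  ccum <- cumsum(seqc == "C")
  count <- function(cum, a, b) { # half-open [a, b), 0-based, b <= L
    (if (b > 0) cum[b] else 0) - (if (a > 0) cum[a] else 0)
  }
  starts <- if (genome@circular) seq(0L, L - 1L, by = step)
            else seq(0L, L - window, by = step)
  nG <- nC <- numeric(length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- a + window
    if (b <= L) {
      nG[i] <- count(gcum, a, b); nC[i] <- count(ccum, a, b)
    } else { # circular wrap
      nG[i] <- count(gcum, a, L) + count(gcum, 0L, b - L)
      nC[i] <- count(ccum, a, L) + count(ccum, 0L, b - L)
    }
  }
  tot <- nG + nC
  skew <- ifelse(tot == 0, 0, (nG - nC) / tot)
  cumulative <- cumsum(skew)

  if (all(skew == 0)) {
    ori <- ter <- NA_real_
  } else {
    bound <- starts + window
    if (genome@circular) bound <- bound %% L
    pick <- function(idx) min(bound[idx]) # tie: smallest genomic coordinate
    ter <- pick(which(cumulative == max(cumulative)))
    ori <- pick(which(cumulative == min(cumulative)))
  }
  new("SkewProfile", window = window, step = step,
      starts = as.numeric(starts), skew = skew, cumulative = cumulative,
      ori_pos = ori, ter_pos = ter, genome_length = as.numeric(L),
      circular = genome@circular)
}
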