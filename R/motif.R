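# matS-discovery scanning: edit-distance / degenerate motif search on
# (circular) genomes, terminus-distance ranking, and global percent identity.

.check_dna <- function(x, name, allow_n = FALSE) {
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  bad <- which(!strsplit(x, "")[[1]] %in% ok)
  if (length(bad))
    .stopf("'%s' contains invalid character(s) at position(s) %s", name,
           paste(head(bad, 10L), collapse = ", "))
  invisible(x)
}

#' Edit distance between two DNA strings
#'
#' Unit-cost Levenshtein distance (substitutions, insertions, deletions), or
#' the indel-free Hamming distance between equal-length strings. This is the
#' distance underlying degenerate matS-site discovery.
#'
#' @param a,b DNA strings over A/C/G/T (uppercase).
#' @param method `"levenshtein"` (default) or `"hamming"`.
#' @return Integer distance.
#' @examples
#' editDistance("GTGACATTGTCAC", "GTTACATTGTAAC")
#' @export
editDistance <- function(a, b, method = c("levenshtein", "hamming")) {
  method <- match.arg(method)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nzchar(a)) .check_dna(a, "a")
  if (nzchar(b)) .check_dna(b, "b")
  if (method == "hamming") {
    if (nchar(a) != nchar(b))
      .stopf("hamming distance requires equal-length strings (%d vs %d)",
             nchar(a), nchar(b))
    return(sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
  .edit_distance_cpp(a, b)
}

# Reverse complement preserving N.
.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

.is_palindromic <- function(pattern) identical(pattern, .revcomp(pattern))

# Merge overlapping hits of one scanned pattern: among starts closer than the
# pattern length keep the minimum distance, then the smallest start.
.collapse_hits <- function(df, m, L, circular) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$start, df$edit_distance), , drop = FALSE]
  grp <- cumsum(c(1L, diff(df$start) >= m))
  if (circular && length(unique(grp)) > 1L) {
    # first and last group may abut across the origin
    first <- grp == grp[1L]
    last <- grp == grp[length(grp)]
    if ((df$start[1L] + L - df$start[nrow(df)]) < m) grp[last] <- grp[1L]
  }
  keep <- unlist(lapply(split(seq_len(nrow(df)), grp), function(idx) {
    sub <- df[idx, , drop = FALSE]
    idx[order(sub$edit_distance, sub$start)[1L]]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

#' Scan a genome for degenerate or edit-distance motif matches
#'
#' Locates all sites matching `pattern` within `maxEdit` edits. With
#' `maxEdit = 0` and `N` wildcards in the pattern this is degenerate exact
#' matching (N matches any base); with `maxEdit > 0` every locus whose local
#' window (lengths `|pattern| - maxEdit` to `|pattern| + maxEdit`) lies
#' within `maxEdit` Levenshtein edits of the pattern is reported with the
#' minimum distance. Circular genomes are scanned across the origin.
#' Palindromic patterns match both strands at the same locus and are
#' reported once on the forward strand; non-palindromic patterns are also
#' scanned as their reverse complement when `bothStrands` is `TRUE`.
#'
#' @param genome A [CircularGenome-class].
#' @param pattern IUPAC string over A/C/G/T/N.
#' @param maxEdit Maximum edit distance (the matS scan uses 2).
#' @param method `"edit"` for Levenshtein (default) or `"hamming"` for
#'   substitution-only matching within fixed-length windows.
#' @param bothStrands Scan the reverse complement of non-palindromic
#'   patterns (default `TRUE`).
#' @param collapseOverlaps Merge overlapping hits of the same pattern,
#'   keeping the minimum-distance representative (default `TRUE`).
#' @return A [GenomicRanges::GRanges] on the forward strand coordinate
#'   system with metadata columns `edit_distance`, `matched_seq` and
#'   `pattern`. Coordinates are 1-based closed within R; exported TSVs use
#'   0-based half-open coordinates.
#' @examples
#' g <- CircularGenome("toy", "AAGTTACATTGTAACAA")
#' scanMotifs(g, "GTTACNNNGTAAC", maxEdit = 0)
#' @export
scanMotifs <- function(genome, pattern, maxEdit = 0L,
                       method = c("edit", "hamming"), bothStrands = TRUE,
                       collapseOverlaps = TRUE) {
  method <- match.arg(method)
  stopifnot(is(genome, "CircularGenome"))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    .stopf("'pattern' must be a non-empty string")
  pattern <- toupper(pattern)
  .check_dna(pattern, "pattern", allow_n = TRUE)
  maxEdit <- as.integer(maxEdit)
  if (maxEdit < 0L) .stopf("'maxEdit' must be >= 0")
  m <- nchar(pattern)
  L <- length(genome)
  if (m > L) .stopf("pattern (%d bp) is longer than the genome (%d bp)", m, L)

  text <- as.character(genome@seq)
  circular <- isCircular(genome)
  ext <- if (circular) paste0(text, substr(text, 1L, m + maxEdit - 1L)) else text

  scan_one <- function(pat, strand) {
    df <- if (method == "edit") {
      .scan_edit_cpp(ext, pat, maxEdit, L)
    } else {
      .scan_hamming_cpp(ext, pat, maxEdit, L)
    }
    df <- as.data.frame(df)
    if (nrow(df) == 0L) return(cbind(df, strand = character(0)))
    if (collapseOverlaps) df <- .collapse_hits(df, m, L, circular)
    df$strand <- strand
    df
  }

  pal <- .is_palindromic(pattern)
  hits <- scan_one(pattern, "+")
  if (!pal && bothStrands) {
    rc <- scan_one(.revcomp(pattern), "-")
    hits <- rbind(hits, rc)
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]

  si <- GenomeInfoDb::Seqinfo(seqnames = genome@name, seqlengths = L,
                              isCircular = circular)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome@name, nrow(hits)),
    ranges = IRanges::IRanges(start = hits$start + 1L,
                              width = hits$match_length),
    strand = if (nrow(hits)) hits$strand else character(0),
    seqinfo = si)
  matched <- vapply(seq_len(nrow(hits)), function(i)
    substr(ext, hits$start[i] + 1L, hits$start[i] + hits$match_length[i]),
    character(1))
  S4Vectors::mcols(gr)$edit_distance <- hits$edit_distance
  S4Vectors::mcols(gr)$matched_seq <- matched
  S4Vectors::mcols(gr)$pattern <- rep(pattern, nrow(hits))
  gr
}

#' Circular distance between two genomic coordinates
#'
#' Shortest distance on a circle of given length; never exceeds `length/2`.
#'
#' @param i,j Coordinates in `[0, length)` (vectorised).
#' @param length Circle length in bp (> 0).
#' @return Numeric distance(s).
#' @examples
#' circularDistance(1, 9, 10) # 2, wrapping the origin
#' @export
circularDistance <- function(i, j, length) {
  if (!is.numeric(length) || length[1L] <= 0)
    .stopf("'length' must be positive")
  if (any(i < 0 | i >= length | j < 0 | j >= length))
    .stopf("coordinates must lie in [0, length)")
  d <- abs(i - j)
  pmin(d, length - d)
}

#' Rank motif families by median circular distance to the terminus
#'
#' Implements the site-family ranking of the matS discovery procedure:
#' per family, the median of circular distances from hit midpoints to the
#' replication terminus; families sorted ascending (rank 1 = closest to the
#' terminus), ties broken lexicographically by pattern.
#'
#' @param hits Named list, one element per family pattern: either a
#'   [GenomicRanges::GRanges] from [scanMotifs()] or a numeric vector of
#'   0-based hit midpoints.
#' @param terPos 0-based terminus coordinate.
#' @param genomeLength Genome length in bp.
#' @return A `data.frame` with columns `family_pattern`, `n_hits`,
#'   `median_ter_distance`, `rank`, sorted by rank.
#' @export
rankSiteFamilies <- function(hits, terPos, genomeLength) {
  if (!is.list(hits) || length(hits) == 0L || is.null(names(hits)) ||
      any(!nzchar(names(hits))))
    .stopf("'hits' must be a non-empty named list (names = family patterns)")
  .assert_scalar_num(terPos, "terPos")
  .assert_scalar_num(genomeLength, "genomeLength")
  rows <- lapply(names(hits), function(fam) {
    h <- hits[[fam]]
    mids <- if (is(h, "GRanges")) {
      ((GenomicRanges::start(h) - 1) + GenomicRanges::width(h) / 2) %% genomeLength
    } else {
      as.numeric(h) %% genomeLength
    }
    if (length(mids) == 0L) .stopf("family '%s' has no hits", fam)
    d <- circularDistance(mids, rep(terPos, length(mids)), genomeLength)
    data.frame(family_pattern = fam, n_hits = length(mids),
               median_ter_distance = median(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$median_ter_distance, out$family_pattern), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1 (defaults); identity is 100 x matched columns / total
#' alignment columns (gap columns included in the denominator).
#'
#' @param a,b Non-empty sequences (nucleotide or amino acid).
#' @param match,mismatch,gap Alignment scores (gap is the per-symbol linear
#'   penalty, given as a positive cost).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' globalIdentity("ACGTT", "ACGT") # 80: 4 matches over 5 columns
#' @export
globalIdentity <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  if (!nzchar(a) || !nzchar(b)) .stopf("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  chars <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  mat <- matrix(mismatch, length(chars), length(chars),
                dimnames = list(chars, chars))
  diag(mat) <- match
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(pa == sb & pa != "-") / length(pa)
}
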