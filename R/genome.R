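#' CircularGenome: a DNA sequence with circular topology
#'
#' Container for a single chromosome or plasmid sequence over the strict
#' \{A,C,G,T\} alphabet. Circular topology changes how motif scans and
#' distance computations wrap around the origin.
#'
#' @slot name Single-record sequence name.
#' @slot seq A [Biostrings::DNAString] restricted to A/C/G/T.
#' @slot circular Logical topology flag.
#'
#' @examples
#' g <- CircularGenome("toy", "ACGTACGT", circular = TRUE)
#' length(g)
#' isCircular(g)
#' @exportClass CircularGenome
setClass("CircularGenome",
  representation(name = "character", seq = "DNAString", circular = "logical"))

setValidity("CircularGenome", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  if (length(object@seq) < 1L)
    msgs <- c(msgs, "sequence must have length >= 1")
  freq <- Biostrings::alphabetFrequency(object@seq)
  extra <- freq[setdiff(names(freq), c("A", "C", "G", "T"))]
  if (sum(extra) > 0L) {
    bad <- names(extra)[extra > 0L]
    msgs <- c(msgs, sprintf(
      "sequence contains non-ACGT characters (%s); ambiguity codes are not supported",
      paste(bad, collapse = ", ")))
  }
  if (length(object@circular) != 1L || is.na(object@circular))
    msgs <- c(msgs, "'circular' must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' @param name Sequence name.
#' @param seq Character string or [Biostrings::DNAString] over A/C/G/T
#'   (lowercase accepted and normalised).
#' @param circular Logical; circular topology (default `FALSE`).
#' @rdname CircularGenome-class
#' @export
CircularGenome <- function(name, seq, circular = FALSE) {
  if (is.character(seq)) {
    seq <- toupper(seq)
    bad <- which(!strsplit(seq, "")[[1]] %in% c("A", "C", "G", "T"))
    if (length(bad))
      .stopf("non-ACGT character(s) at position(s) %s",
             paste(head(bad, 10L), collapse = ", "))
    seq <- Biostrings::DNAString(seq)
  }
  new("CircularGenome", name = as.character(name), seq = seq,
      circular = isTRUE(circular))
}

#' @export
setMethod("length", "CircularGenome", function(x) length(x@seq))

#' @export
setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d bp, %s\n", object@name,
              length(object@seq),
              if (object@circular) "circular" else "linear"))
})

#' @rdname CircularGenome-class
#' @param x,object A `CircularGenome`.
#' @export
genomeSeq <- function(x) x@seq

#' @rdname CircularGenome-class
#' @export
genomeName <- function(x) x@name

#' Is a genome circular?
#'
#' @param x A [CircularGenome-class].
#' @return Logical.
#' @export
isCircular <- function(x) x@circular

#' Read a single-record FASTA file into a CircularGenome
#'
#' The header may carry a `circular=true` (or `false`) token; absence means
#' linear. Lowercase bases are normalised to uppercase; ambiguity codes are
#' rejected with the offending positions.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A [CircularGenome-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy circular=true", "acgtACGT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    .stopf("expected a single-record FASTA, but '%s' contains %d records",
           path, length(set))
  header <- names(set)[1L]
  seq <- toupper(as.character(set[[1L]]))
  bad <- which(!strsplit(seq, "")[[1]] %in% c("A", "C", "G", "T"))
  if (length(bad))
    .stopf("'%s': non-ACGT character(s) at position(s) %s", path,
           paste(head(bad, 10L), collapse = ", "))
  circ <- grepl("\\bcircular=true\\b", header, ignore.case = TRUE)
  name <- strsplit(header, "\\s+")[[1]][1L]
  CircularGenome(name, seq, circular = circ)
}

#' Write a CircularGenome as FASTA
#'
#' The topology is recorded as a `circular=true|false` header token so that
#' [readFasta()] round-trips it.
#'
#' @param genome A [CircularGenome-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(genome, path) {
  stopifnot(is(genome, "CircularGenome"))
  set <- Biostrings::DNAStringSet(genome@seq)
  names(set) <- sprintf("%s circular=%s", genome@name,
                        if (genome@circular) "true" else "false")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
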