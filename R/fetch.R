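# Accession-based retrieval for reproducing published measurements on the
# deposited data. These helpers require network access; all other package
# functionality is network-free.

#' Fetch a nucleotide record from NCBI as FASTA
#'
#' Downloads `https://eutils.ncbi.nlm.nih.gov` efetch output into
#' `destdir` (skipped when a cached copy exists) and returns the file path.
#'
#' @param accession NCBI nucleotide accession (e.g. a chromosome record).
#' @param destdir Cache directory (created if needed).
#' @return Path to the downloaded FASTA file.
#' @export
fetchGenomeFasta <- function(accession, destdir = tempdir()) {
  dir.create(destdir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(destdir, paste0(accession, ".fasta"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    .stopf("could not download accession %s (network unavailable?)", accession)
  }
  dest
}

#' Fetch a protein record from NCBI as FASTA
#'
#' @inheritParams fetchGenomeFasta
#' @return Path to the downloaded FASTA file.
#' @export
fetchProteinFasta <- function(accession, destdir = tempdir()) {
  dir.create(destdir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(destdir, paste0(accession, ".fasta"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=protein&rettype=fasta&retmode=text&id=", accession)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    .stopf("could not download accession %s (network unavailable?)", accession)
  }
  dest
}

#' Fetch a PDB entry from the RCSB
#'
#' @param pdbId 4-character PDB identifier.
#' @param destdir Cache directory.
#' @param format `"pdb"` or `"cif"`.
#' @return Path to the downloaded structure file.
#' @export
fetchPDB <- function(pdbId, destdir = tempdir(), format = c("pdb", "cif")) {
  format <- match.arg(format)
  dir.create(destdir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(destdir, paste0(toupper(pdbId), ".", format))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.%s", toupper(pdbId),
                 format)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    .stopf("could not download PDB %s (network unavailable?)", pdbId)
  }
  dest
}
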