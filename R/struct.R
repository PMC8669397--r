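# Structural measurements: PDB/mmCIF reading, duplex helix-axis fitting,
# inter-duplex crossing angle, and minimum backbone VDW distance.

.NUCLEIC_RESID <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U")
.PROTEIN_BACKBONE <- c("N", "CA", "C", "O")
.NUCLEIC_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

#' StructureModel: atomic coordinates of a macromolecular model
#'
#' @slot atoms `data.frame` with columns `chain_id`, `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`.
#' @slot source_format `"PDB"` or `"mmCIF"`.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(atoms = "data.frame", source_format = "character"))

setValidity("StructureModel", function(object) {
  at <- object@atoms
  req <- c("chain_id", "residue_number", "residue_name", "atom_name",
           "element", "x", "y", "z")
  if (!all(req %in% names(at)))
    return(paste("atoms need columns", paste(req, collapse = ", ")))
  if (nrow(at) == 0L) return("empty model")
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
    return("coordinates must be finite")
  if (any(!nzchar(at$chain_id)) || any(is.na(at$residue_number)))
    return("chain and residue identifiers must be non-empty")
  TRUE
})

#' @param atoms,source_format See the class slots.
#' @rdname StructureModel-class
#' @export
StructureModel <- function(atoms, source_format = "PDB") {
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  new("StructureModel", atoms = atoms, source_format = source_format)
}

#' @export
setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  cat(sprintf("StructureModel (%s): %d atoms, %d chain(s): %s\n",
              object@source_format, nrow(at),
              length(unique(at$chain_id)),
              paste(sort(unique(at$chain_id)), collapse = ", ")))
})

#' @rdname StructureModel-class
#' @param x A `StructureModel`.
#' @export
structureAtoms <- function(x) x@atoms

# Derive an element symbol from a PDB atom name.
.element_from_name <- function(atom_name) {
  vapply(atom_name, function(nm) {
    letters_only <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(letters_only)) return("X")
    toupper(substr(letters_only, 1L, 1L))
  }, character(1), USE.NAMES = FALSE)
}

# Highest-occupancy-then-'A' alternate location policy.
.resolve_altloc <- function(at, alt, occ) {
  key <- paste(at$chain_id, at$residue_number, at$atom_name, sep = "\r")
  alt[is.na(alt)] <- ""
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt != "A" & alt != "", alt)
  keep <- ord[!duplicated(key[ord])]
  at[sort(keep), , drop = FALSE]
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Loads all atoms of the first model; alternate locations are resolved to
#' the highest occupancy (then altloc 'A'). The format is auto-detected
#' from the file extension and can be overridden.
#'
#' @param path Structure file path.
#' @param format `"auto"` (default), `"pdb"` or `"cif"`.
#' @return A [StructureModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("structure file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE) else
        bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                        verbose = FALSE)),
    error = function(e) .stopf("could not parse '%s' as %s: %s", path,
                               toupper(format), conditionMessage(e)))
  raw <- parsed$atom
  if (is.null(raw) || nrow(raw) == 0L) .stopf("'%s': empty model", path)
  chain <- as.character(raw$chain)
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  elem <- toupper(as.character(raw$elesy))
  miss <- is.na(elem) | !nzchar(elem)
  elem[miss] <- .element_from_name(raw$elety[miss])
  at <- data.frame(chain_id = chain,
                   residue_number = as.integer(raw$resno),
                   residue_name = as.character(raw$resid),
                   atom_name = as.character(raw$elety),
                   element = elem,
                   x = raw$x, y = raw$y, z = raw$z,
                   occupancy = if (is.null(raw$o)) 1 else as.numeric(raw$o),
                   stringsAsFactors = FALSE)
  at <- .resolve_altloc(at, as.character(raw$alt), at$occupancy)
  StructureModel(at, source_format = if (format == "cif") "mmCIF" else "PDB")
}

#' Write a StructureModel as a PDB file
#'
#' Minimal fixed-width ATOM record writer, sufficient for the generated
#' helix scenes and fixtures produced by this package; [readStructure()]
#' round-trips its output.
#'
#' @param model A [StructureModel-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  name4 <- ifelse(nchar(at$atom_name) < 4L, paste0(" ", at$atom_name),
                  at$atom_name)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000L, name4, at$residue_name,
    substr(at$chain_id, 1L, 1L), at$residue_number, at$x, at$y, at$z,
    at$occupancy, 0, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Parse atom selections of the form "chain:first-last"
#'
#' Accepts a character vector of `"A"`, `"A:12-55"` or `"A:12-55,B:3-9"`
#' tokens and returns the matching atom row indices.
#'
#' @param model A [StructureModel-class].
#' @param selection Selection string(s).
#' @return Integer vector of row indices into `structureAtoms(model)`.
#' @export
selectAtoms <- function(model, selection) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  tokens <- unlist(strsplit(selection, ","))
  idx <- integer(0)
  for (tok in tokens) {
    tok <- trimws(tok)
    parts <- strsplit(tok, ":")[[1]]
    sel <- at$chain_id == parts[1L]
    if (length(parts) > 1L) {
      rng <- suppressWarnings(as.integer(strsplit(parts[2L], "-")[[1]]))
      if (length(rng) != 2L || any(is.na(rng)))
        .stopf("malformed selection token '%s' (expected chain:first-last)", tok)
      sel <- sel & at$residue_number >= rng[1L] & at$residue_number <= rng[2L]
    }
    idx <- union(idx, which(sel))
  }
  sort(idx)
}

#' HelixAxisFit: a fitted DNA duplex axis
#'
#' @slot direction Unit direction vector (first to last base pair).
#' @slot point Centroid of the base-pair midpoints (a point on the axis).
#' @slot n_basepairs_used Number of base pairs in the fit (>= 4).
#' @slot rms_axial_deviation RMS perpendicular deviation of midpoints from
#'   the fitted line, in Angstrom.
#' @exportClass HelixAxisFit
setClass("HelixAxisFit",
  representation(direction = "numeric", point = "numeric",
                 n_basepairs_used = "integer", rms_axial_deviation = "numeric"))

setValidity("HelixAxisFit", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("'direction' must be a unit vector")
  if (object@n_basepairs_used < 4L) return("at least 4 base pairs required")
  TRUE
})

#' @export
setMethod("show", "HelixAxisFit", function(object) {
  cat(sprintf("HelixAxisFit: %d bp, direction (%.3f, %.3f, %.3f), rms %.3g A\n",
              object@n_basepairs_used, object@direction[1L],
              object@direction[2L], object@direction[3L],
              object@rms_axial_deviation))
})

#' @rdname HelixAxisFit-class
#' @param x A `HelixAxisFit`.
#' @export
axisDirection <- function(x) x@direction

#' Fit a DNA duplex helix axis from base-pair midpoints
#'
#' Pairs the two strand selections antiparallel by index, computes the
#' midpoint of the paired C1' atoms (falling back to P when C1' is absent),
#' and fits a total-least-squares line through the midpoints. The direction
#' points from the first to the last base pair.
#'
#' @param model A [StructureModel-class].
#' @param strandA,strandB Selections (see [selectAtoms()]) for the two
#'   strands, each covering the same number of residues (>= 4).
#' @return A [HelixAxisFit-class].
#' @export
fitDuplexAxis <- function(model, strandA, strandB) {
  stopifnot(is(model, "StructureModel"))
  anchor <- function(sel, reverse) {
    at <- model@atoms[selectAtoms(model, sel), , drop = FALSE]
    if (nrow(at) == 0L) .stopf("selection '%s' matches no atoms", sel)
    res <- split(at, at$residue_number)
    res <- res[order(as.integer(names(res)), decreasing = reverse)]
    bad <- character(0)
    pts <- t(vapply(res, function(r) {
      hit <- r[r$atom_name %in% c("C1'", "C1*"), , drop = FALSE]
      if (nrow(hit) == 0L) hit <- r[r$atom_name == "P", , drop = FALSE]
      if (nrow(hit) == 0L) {
        bad <<- c(bad, sprintf("%s:%d", r$chain_id[1L], r$residue_number[1L]))
        return(c(NA_real_, NA_real_, NA_real_))
      }
      unlist(hit[1L, c("x", "y", "z")])
    }, numeric(3)))
    if (length(bad))
      .stopf("no C1' or P atom in residue(s) %s", paste(bad, collapse = ", "))
    pts
  }
  a <- anchor(strandA, reverse = FALSE)
  b <- anchor(strandB, reverse = TRUE) # antiparallel pairing by index
  if (nrow(a) != nrow(b))
    .stopf("strand selections differ in residue count (%d vs %d)",
           nrow(a), nrow(b))
  if (nrow(a) < 4L) .stopf("at least 4 base pairs are required, got %d", nrow(a))
  mid <- (a + b) / 2
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2L, ctr))
  dir <- sv$v[, 1L]
  if (sum(dir * (mid[nrow(mid), ] - mid[1L, ])) < 0) dir <- -dir
  proj <- as.numeric(sweep(mid, 2L, ctr) %*% dir)
  resid <- sweep(mid, 2L, ctr) - outer(proj, dir)
  new("HelixAxisFit", direction = dir / sqrt(sum(dir^2)), point = ctr,
      n_basepairs_used = nrow(mid),
      rms_axial_deviation = sqrt(mean(rowSums(resid^2))))
}

#' Crossing angle between two fitted helix axes
#'
#' Acute convention (default): `acos(|a . b|)` in `[0, 90]` degrees,
#' invariant under flipping either axis. Signed convention (experimental):
#' the acute magnitude signed by the triple product with the inter-axis
#' connector, in `(-90, 90]`.
#'
#' @param axisA,axisB [HelixAxisFit-class] objects.
#' @param convention `"acute"` (default) or `"signed"`.
#' @return Angle in degrees.
#' @export
crossingAngle <- function(axisA, axisB, convention = c("acute", "signed")) {
  convention <- match.arg(convention)
  stopifnot(is(axisA, "HelixAxisFit"), is(axisB, "HelixAxisFit"))
  a <- axisA@direction; b <- axisB@direction
  if (sqrt(sum(a^2)) < 1e-12 || sqrt(sum(b^2)) < 1e-12)
    .stopf("zero-length axis direction")
  d <- sum(a * b)
  acute <- acos(pmin(abs(d), 1)) * 180 / pi
  if (convention == "acute") return(acute)
  conn <- axisB@point - axisA@point
  cr <- c(a[2L] * b[3L] - a[3L] * b[2L],
          a[3L] * b[1L] - a[1L] * b[3L],
          a[1L] * b[2L] - a[2L] * b[1L])
  s <- sign(sum(cr * conn))
  if (s == 0) s <- 1
  s * acute
}

#' Van der Waals radii tables
#'
#' Bondi-type radii for the elements appearing in protein and nucleic acid
#' backbones. The table is explicit and swappable because published
#' interface measurements rarely state their radii source.
#'
#' @param name Table name; currently `"bondi"`.
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdwRadii <- function(name = "bondi") {
  tables <- list(bondi = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                           S = 1.80, P = 1.80))
  if (!name %in% names(tables))
    .stopf("unknown radii table '%s' (available: %s)", name,
           paste(names(tables), collapse = ", "))
  r <- tables[[name]]
  attr(r, "name") <- name
  r
}

.backbone_rows <- function(at) {
  nucleic <- at$residue_name %in% .NUCLEIC_RESID
  (nucleic & at$atom_name %in% .NUCLEIC_BACKBONE) |
    (!nucleic & at$atom_name %in% .PROTEIN_BACKBONE)
}

#' Minimum backbone van der Waals distance across an interface
#'
#' Restricts both selections to backbone atoms (protein: N, CA, C, O;
#' nucleic residues: P, OP1/2, O5', C5', C4', C3', O3') and minimises
#' \eqn{\lVert x_i - x_j \rVert - r_i - r_j} over all cross pairs. Negative
#' values indicate interpenetrating VDW surfaces. The attaining atom pair is
#' attached as attribute `"pair"`.
#'
#' @param model A [StructureModel-class].
#' @param selA,selB Selections (see [selectAtoms()]).
#' @param radii Named radii vector from [vdwRadii()].
#' @return Minimum VDW distance in Angstrom, with attribute `"pair"` (a
#'   2-row `data.frame` of the attaining atoms).
#' @export
minBackboneVdwDistance <- function(model, selA, selB, radii = vdwRadii()) {
  stopifnot(is(model, "StructureModel"))
  pick <- function(sel) {
    at <- model@atoms[selectAtoms(model, sel), , drop = FALSE]
    at <- at[.backbone_rows(at), , drop = FALSE]
    if (nrow(at) == 0L)
      .stopf("selection '%s' contains no backbone atoms",
             paste(sel, collapse = ","))
    at
  }
  a <- pick(selA); b <- pick(selB)
  miss <- setdiff(unique(c(a$element, b$element)), names(radii))
  if (length(miss))
    .stopf("no VDW radius for element(s): %s", paste(miss, collapse = ", "))
  ra <- radii[a$element]; rb <- radii[b$element]
  best <- Inf; best_i <- best_j <- 1L
  chunk <- max(1L, floor(4e6 / nrow(b)))
  for (start in seq(1L, nrow(a), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(a))
    dx <- outer(a$x[ii], b$x, "-")
    dy <- outer(a$y[ii], b$y, "-")
    dz <- outer(a$z[ii], b$z, "-")
    vd <- sqrt(dx^2 + dy^2 + dz^2) - outer(ra[ii], rb, "+")
    k <- which.min(vd)
    if (vd[k] < best) {
      best <- vd[k]
      best_i <- ii[(k - 1L) %% length(ii) + 1L]
      best_j <- (k - 1L) %/% length(ii) + 1L
    }
  }
  out <- unname(best)
  attr(out, "pair") <- rbind(a[best_i, , drop = FALSE],
                             b[best_j, , drop = FALSE])
  out
}
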