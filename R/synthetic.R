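# Seeded generators for every input class the pipeline consumes, each
# returning the generated object together with its ground truth. Random
# streams are independent per generator call, keyed by (seed, purpose tag),
# and never disturb the caller's RNG state.

#' Generate a circular genome with two replichores and planted motifs
#'
#' Background bases are drawn per replichore with
#' `P(G) - P(C) = +/- skewAmplitude * (P(G) + P(C))` (G-rich from ori to
#' ter, C-rich on the way back, matching the leading-strand G bias that
#' makes the cumulative GC skew peak at the terminus). A and T share the
#' non-GC mass uniformly. Planted motifs overwrite the background with
#' exactly `n_mut` random substitutions each; `N` positions in a planted
#' pattern are instantiated randomly and the realised sequence is recorded.
#'
#' @param length Genome length in bp (>= 1000).
#' @param oriPos 0-based origin position (default 0); the terminus is
#'   placed diametrically opposite.
#' @param skewAmplitude Skew amplitude in `(0, 1]`.
#' @param planted List of site specs `list(pattern =, pos =, n_mut =)`;
#'   positions are 0-based and must not overlap.
#' @param gcContent Genome G+C fraction (default 0.5).
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @return A list (`GenomeTruth`) with elements `genome`
#'   ([CircularGenome-class]), `ori_pos`, `ter_pos`, `planted_sites`
#'   (`data.frame` of `position`, `pattern`, `n_mutations`,
#'   `realized_seq`), `skew_amplitude`, `gc_content`, `seed`.
#' @examples
#' tr <- genGenome(10000, skewAmplitude = 0.3, seed = 7)
#' tr$ter_pos
#' @export
genGenome <- function(length, oriPos = 0L, skewAmplitude = 0.2,
                      planted = list(), gcContent = 0.5, seed = 1L) {
  length <- as.integer(length)
  if (length < 1000L) .stopf("'length' must be >= 1000")
  oriPos <- as.integer(oriPos)
  if (oriPos < 0L || oriPos >= length) .stopf("'oriPos' must lie in [0, length)")
  if (skewAmplitude <= 0 || skewAmplitude > 1)
    .stopf("'skewAmplitude' must lie in (0, 1]")
  if (gcContent <= 0 || gcContent >= 1) .stopf("'gcContent' must lie in (0, 1)")
  ter <- (oriPos + length %/% 2L) %% length

  # planted-site validation: distinct, non-overlapping (with circular wrap)
  if (length(planted)) {
    pos <- vapply(planted, function(s) as.integer(s$pos), integer(1))
    len <- vapply(planted, function(s) nchar(s$pattern), integer(1))
    if (any(pos < 0L | pos >= length)) .stopf("planted positions out of range")
    o <- order(pos)
    pos_o <- pos[o]; len_o <- len[o]
    if (length(pos) > 1L) {
      gaps_ok <- all(pos_o[-1L] >= (pos_o + len_o)[-length(pos_o)])
      wrap_ok <- pos_o[1L] + length >= pos_o[length(pos_o)] + len_o[length(pos_o)]
      if (!gaps_ok || !wrap_ok) .stopf("planted sites overlap")
    }
  }

  .with_seed(seed, "genome", {
    half <- gcContent / 2
    p_lead <- c(A = (1 - gcContent) / 2, C = half * (1 - skewAmplitude),
                G = half * (1 + skewAmplitude), T = (1 - gcContent) / 2)
    p_lag <- c(A = (1 - gcContent) / 2, C = half * (1 + skewAmplitude),
               G = half * (1 - skewAmplitude), T = (1 - gcContent) / 2)
    idx <- 0:(length - 1L)
    lead <- if (oriPos <= ter) idx >= oriPos & idx < ter
            else idx >= oriPos | idx < ter
    bases <- character(length)
    bases[lead] <- sample(names(p_lead), sum(lead), replace = TRUE,
                          prob = p_lead)
    bases[!lead] <- sample(names(p_lag), sum(!lead), replace = TRUE,
                           prob = p_lag)

    site_rows <- lapply(planted, function(s) {
      pat <- toupper(s$pattern)
      .check_dna(pat, "planted pattern", allow_n = TRUE)
      chars <- strsplit(pat, "")[[1]]
      is_n <- chars == "N"
      chars[is_n] <- sample(c("A", "C", "G", "T"), sum(is_n), replace = TRUE)
      n_mut <- as.integer(if (is.null(s$n_mut)) 0L else s$n_mut)
      if (n_mut > 0L) {
        at <- sample(seq_along(chars), n_mut)
        for (i in at)
          chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      }
      tgt <- (as.integer(s$pos) + seq_along(chars) - 1L) %% length
      bases[tgt + 1L] <<- chars
      data.frame(position = as.integer(s$pos), pattern = pat,
                 n_mutations = n_mut,
                 realized_seq = paste(chars, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    sites <- if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(position = integer(0), pattern = character(0),
                 n_mutations = integer(0), realized_seq = character(0))

    structure(list(
      genome = CircularGenome("synthetic_genome",
                              paste(bases, collapse = ""), circular = TRUE),
      ori_pos = oriPos, ter_pos = ter, planted_sites = sites,
      skew_amplitude = skewAmplitude, gc_content = gcContent, seed = seed),
      class = c("GenomeTruth", "list"))
  })
}

#' Generate a gel lane profile with Gaussian bands
#'
#' `profile = polynomial background + sum of Gaussian bands + noise`. Bands
#' are area-normalised Gaussians (`area * dnorm(x, center, width)`), the
#' standard densitometry peak model. The background polynomial is evaluated
#' in the scaled coordinate `u = x / lengthPx` for numerical conditioning.
#'
#' @param bands `data.frame` with columns `center` (px), `width` (px, > 0)
#'   and `area` (a.u., >= 0); may have zero rows.
#' @param backgroundCoefficients Polynomial coefficients, constant term
#'   first.
#' @param noiseSd Gaussian noise standard deviation.
#' @param lengthPx Profile length in pixels.
#' @param seed Integer seed.
#' @return A list (`LaneTruth`) with `profile` ([LaneProfile-class]),
#'   `bands`, `background` (the noise-free background vector),
#'   `background_coefficients`, `noise_sd`, `seed`.
#' @export
genLaneProfile <- function(bands, backgroundCoefficients = 0, noiseSd = 0,
                           lengthPx = 1000L, seed = 1L) {
  lengthPx <- as.integer(lengthPx)
  if (lengthPx < 3L) .stopf("'lengthPx' must be >= 3")
  if (is.null(bands)) bands <- data.frame(center = numeric(0),
                                          width = numeric(0),
                                          area = numeric(0))
  bands <- as.data.frame(bands)
  if (nrow(bands)) {
    if (!all(c("center", "width", "area") %in% names(bands)))
      .stopf("'bands' needs columns center, width, area")
    if (any(bands$center < 0 | bands$center >= lengthPx))
      .stopf("band centers must lie in [0, lengthPx)")
    if (any(bands$width <= 0)) .stopf("band widths must be positive")
    if (any(bands$area < 0)) .stopf("band areas must be >= 0")
  }
  x <- as.numeric(0:(lengthPx - 1L))
  u <- x / lengthPx
  bg <- rep(0, lengthPx)
  for (k in seq_along(backgroundCoefficients))
    bg <- bg + backgroundCoefficients[k] * u^(k - 1)
  y <- bg
  for (i in seq_len(nrow(bands)))
    y <- y + bands$area[i] * dnorm(x, bands$center[i], bands$width[i])
  if (noiseSd > 0)
    y <- y + .with_seed(seed, "lane", rnorm(lengthPx, 0, noiseSd))
  structure(list(profile = LaneProfile(x, y), bands = bands,
                 background = bg,
                 background_coefficients = backgroundCoefficients,
                 noise_sd = noiseSd, seed = seed),
            class = c("LaneTruth", "list"))
}

#' Generate an EMSA titration from the equilibrium binding curve
#'
#' Responses are the depletion-aware equilibrium bound fraction affinely
#' mapped to `[baseline, asymptote]`, plus Gaussian noise.
#'
#' @param trueKd True dissociation constant in nM (> 0).
#' @param baseline,asymptote Affine response mapping (must differ, else the
#'   titration is unidentifiable).
#' @param proteinConcs Protein concentrations in nM (>= 0).
#' @param dnaTotal Total DNA in nM (default 2, the labelled-probe scale).
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A list (`TitrationTruth`) with `series`
#'   ([TitrationSeries-class]), `true_Kd`, `true_baseline`,
#'   `true_asymptote`, `noise_sd`, `seed`.
#' @export
genTitration <- function(trueKd, baseline, asymptote, proteinConcs,
                         dnaTotal = 2, noiseSd = 0, seed = 1L) {
  .assert_scalar_num(trueKd, "trueKd")
  if (trueKd <= 0) .stopf("'trueKd' must be positive")
  if (asymptote == baseline)
    .stopf("'asymptote' must differ from 'baseline' (unidentifiable)")
  if (any(proteinConcs < 0)) .stopf("concentrations must be >= 0")
  f <- equilibriumBoundFraction(proteinConcs, dnaTotal, trueKd)
  y <- baseline + (asymptote - baseline) * f
  if (noiseSd > 0)
    y <- y + .with_seed(seed, "titration",
                        rnorm(length(proteinConcs), 0, noiseSd))
  structure(list(series = TitrationSeries(proteinConcs, dnaTotal, y),
                 true_Kd = trueKd, true_baseline = baseline,
                 true_asymptote = asymptote, noise_sd = noiseSd, seed = seed),
            class = c("TitrationTruth", "list"))
}

# One ideal duplex along +z, centered at the origin: C1' anchor atoms of
# the two antiparallel strands on a cylinder. Paired anchors sit
# diametrically across the cylinder so base-pair midpoints lie exactly on
# the helix axis, making the midpoint line fit exact by construction.
.ideal_duplex <- function(n_bp, rise, twist, chain_ids, radius = 9.4,
                          pair_offset = 180) {
  theta <- (seq_len(n_bp) - 1) * twist * pi / 180
  z <- (seq_len(n_bp) - 1) * rise
  z <- z - mean(z)
  s1 <- data.frame(chain_id = chain_ids[1L], residue_number = seq_len(n_bp),
                   residue_name = rep(c("DA", "DT"), length.out = n_bp),
                   atom_name = "C1'", element = "C",
                   x = radius * cos(theta), y = radius * sin(theta), z = z,
                   occupancy = 1, stringsAsFactors = FALSE)
  phi <- theta + pair_offset * pi / 180
  s2 <- data.frame(chain_id = chain_ids[2L],
                   residue_number = rev(seq_len(n_bp)),
                   residue_name = rep(c("DT", "DA"), length.out = n_bp),
                   atom_name = "C1'", element = "C",
                   x = radius * cos(phi), y = radius * sin(phi), z = z,
                   occupancy = 1, stringsAsFactors = FALSE)
  rbind(s1, s2)
}

#' Generate a two-duplex scene with an exact crossing angle
#'
#' Builds two ideal B-form duplexes (rise 3.4 A/bp, twist 36 deg/bp, C1'
#' anchor atoms on a 9.4 A cylinder) whose axes subtend exactly `angle`:
#' each duplex is rotated by `angle/2` about the y axis in opposite
#' directions, and the second is translated 15 A along y. Chains are A/B
#' (duplex 1) and C/D (duplex 2). Construction is deterministic; `seed` is
#' accepted for interface symmetry with the other generators.
#'
#' @param angle Crossing angle in degrees, `[0, 90]`.
#' @param nBp Base pairs per duplex (>= 8).
#' @param rise,twist Helical rise (A/bp) and twist (deg/bp).
#' @param seed Integer seed (unused; the scene is deterministic).
#' @return A list (`HelixSceneTruth`) with `scene`
#'   ([StructureModel-class]), `true_angle`, `true_axes` (2 x 3 matrix of
#'   unit axis directions), `rise_per_bp`, `twist_per_bp`, `n_bp`, `seed`.
#' @examples
#' tr <- genHelixScene(60, 20)
#' crossingAngle(fitDuplexAxis(tr$scene, "A", "B"),
#'               fitDuplexAxis(tr$scene, "C", "D"))
#' @export
genHelixScene <- function(angle, nBp, rise = 3.4, twist = 36, seed = 1L) {
  .assert_scalar_num(angle, "angle")
  if (angle < 0 || angle > 90) .stopf("'angle' must lie in [0, 90] degrees")
  nBp <- as.integer(nBp)
  if (nBp < 8L) .stopf("'nBp' must be >= 8")
  rot_y <- function(df, phi) {
    phi <- phi * pi / 180
    x <- df$x * cos(phi) + df$z * sin(phi)
    z <- -df$x * sin(phi) + df$z * cos(phi)
    df$x <- x; df$z <- z
    df
  }
  d1 <- rot_y(.ideal_duplex(nBp, rise, twist, c("A", "B")), angle / 2)
  d2 <- rot_y(.ideal_duplex(nBp, rise, twist, c("C", "D")), -angle / 2)
  d2$y <- d2$y + 15
  half <- angle / 2 * pi / 180
  axes <- rbind(c(sin(half), 0, cos(half)), c(-sin(half), 0, cos(half)))
  structure(list(scene = StructureModel(rbind(d1, d2)),
                 true_angle = angle, true_axes = axes, rise_per_bp = rise,
                 twist_per_bp = twist, n_bp = nBp, seed = seed),
            class = c("HelixSceneTruth", "list"))
}

#' Generate normally distributed replicate measurements
#'
#' @param mu,sigma Mean and standard deviation (`sigma >= 0`; 0 gives
#'   identical replicates).
#' @param n Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return A list with `replicates` ([ReplicateSet-class]), `true_mu`,
#'   `true_sigma`, `seed`.
#' @export
genReplicates <- function(mu, sigma, n, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) .stopf("'n' must be >= 2")
  if (sigma < 0) .stopf("'sigma' must be >= 0")
  values <- .with_seed(seed, "replicates", rnorm(n, mu, sigma))
  list(replicates = ReplicateSet(values), true_mu = mu, true_sigma = sigma,
       seed = seed)
}
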