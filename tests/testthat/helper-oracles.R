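# Independent oracles and fixture builders. Each oracle is deliberately
# written with different machinery than the implementation it checks
# (utils::adist, brute-force loops, linear-grid integration, igraph).

# --- string distances -------------------------------------------------------

oracle_levenshtein <- function(a, b) {
  drop(utils::adist(a, b))
}

# Brute-force degenerate scan: fixed-length windows, N matches anything.
oracle_degenerate_scan <- function(text, pattern) {
  m <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (s in 0:(nchar(text) - m)) {
    win <- strsplit(substr(text, s + 1, s + m), "")[[1]]
    if (all(pat == "N" | pat == win)) hits <- c(hits, s)
  }
  hits
}

# Brute-force edit scan: for each start, the minimum adist over window
# lengths m-k .. m+k anchored at that start.
oracle_edit_scan <- function(text, pattern, k) {
  m <- nchar(pattern)
  L <- nchar(text)
  out <- data.frame(start = integer(0), dist = integer(0))
  for (s in 0:(L - 1)) {
    lens <- (m - k):(m + k)
    lens <- lens[lens >= 0 & s + lens <= L]
    if (!length(lens)) next
    d <- min(vapply(lens, function(l)
      oracle_levenshtein(pattern, substr(text, s + 1, s + l)), numeric(1)))
    if (d <= k) out <- rbind(out, data.frame(start = s, dist = d))
  }
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- posterior: 2-D brute-force grid integration ---------------------------

# Linear (not log) sigma grid, plain double summation; equal-tailed interval
# by CDF interpolation. Same prior box and sigma truncation as the
# implementation defaults, arithmetic entirely independent.
oracle_posterior_mu <- function(x, level = 0.95, mu_lo = 0, mu_hi = 1,
                                n_mu = 2001, n_sigma = 1200) {
  n <- length(x)
  rng <- diff(range(x))
  sig <- seq(1e-4 * rng, 10 * rng, length.out = n_sigma)
  mu <- seq(mu_lo, mu_hi, length.out = n_mu)
  dens <- numeric(n_mu)
  for (i in seq_len(n_mu)) {
    S <- sum((x - mu[i])^2)
    f <- sig^(-(n + 2)) * exp(-S / (2 * sig^2))
    dens[i] <- sum((f[-1] + f[-n_sigma]) / 2 * diff(sig))
  }
  dens <- dens / sum((dens[-1] + dens[-n_mu]) / 2 * diff(mu))
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_mu]) / 2 * diff(mu)))
  cdf <- cdf / cdf[n_mu]
  q <- function(p) stats::approx(cdf, mu, xout = p, ties = "ordered")$y
  list(lo = q((1 - level) / 2), hi = q(1 - (1 - level) / 2),
       mean = sum(mu * dens) / sum(dens))
}

# --- graph cycles via igraph (independent route) ---------------------------

# Elementary cycles of a multigraph by edge-subset enumeration, using
# igraph for degrees and connectivity.
oracle_cycles <- function(edges_a, edges_b, names) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  nf <- length(names)
  found <- list()
  for (mask in seq_len(2^nf) - 1L) {
    if (mask == 0L) next
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nf) - 1L)) != 0L)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges_a[idx], to = edges_b[idx]), directed = FALSE)
    if (igraph::count_components(g) == 1L &&
        all(igraph::degree(g, loops = TRUE) == 2))
      found <- c(found, list(sort(names[idx])))
  }
  found
}

# --- VDW: all-pairs double loop --------------------------------------------

oracle_min_vdw <- function(xyz_a, r_a, xyz_b, r_b) {
  best <- Inf
  for (i in seq_len(nrow(xyz_a)))
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2)) - r_a[i] - r_b[j]
      if (d < best) best <- d
    }
  best
}

# --- geometry helpers -------------------------------------------------------

random_rotation <- function() {
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

transform_model <- function(model, R, t) {
  at <- structureAtoms(model)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + t[1]; at$y <- xyz[, 2] + t[2]; at$z <- xyz[, 3] + t[3]
  StructureModel(at, model@source_format)
}

# --- tiny structure fixtures ------------------------------------------------

# Five backbone atoms with hand-checkable pairwise distances.
toy_protein_model <- function() {
  at <- data.frame(
    chain_id = c("A", "A", "A", "B", "B"),
    residue_number = c(1L, 1L, 1L, 1L, 2L),
    residue_name = "GLY",
    atom_name = c("N", "CA", "C", "CA", "O"),
    element = c("N", "C", "C", "C", "O"),
    x = c(0, 1.5, 3.0, 0.0, 10.0),
    y = c(0, 0.0, 0.0, 4.0, 0.0),
    z = c(0, 0.0, 0.0, 0.0, 0.0),
    occupancy = 1, stringsAsFactors = FALSE)
  StructureModel(at)
}

toy_pdb_text <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C",
  "END")

toy_cif_text <- c(
  "data_toy",
  "loop_",
  "_atom_site.group_PDB",
  "_atom_site.id",
  "_atom_site.type_symbol",
  "_atom_site.label_atom_id",
  "_atom_site.label_alt_id",
  "_atom_site.label_comp_id",
  "_atom_site.label_asym_id",
  "_atom_site.label_entity_id",
  "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code",
  "_atom_site.Cartn_x",
  "_atom_site.Cartn_y",
  "_atom_site.Cartn_z",
  "_atom_site.occupancy",
  "_atom_site.B_iso_or_equiv",
  "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id",
  "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id",
  "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 0.00 1 GLY A N 1",
  "ATOM 2 C CA . GLY A 1 1 ? 1.500 0.000 0.000 1.00 0.00 1 GLY A CA 1")

# Shared cache for accession-based checks (network required to populate).
accession_cache <- function() {
  d <- file.path(tempdir(), "muklock-accessions")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
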