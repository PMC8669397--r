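test_that("generators are bit-reproducible for a fixed seed and do not disturb the caller RNG", {
  g1 <- genGenome(10000, skewAmplitude = 0.2, seed = 7)
  set.seed(123); before <- rnorm(1)
  g2 <- genGenome(10000, skewAmplitude = 0.2, seed = 7)
  expect_identical(as.character(genomeSeq(g1$genome)),
                   as.character(genomeSeq(g2$genome)))
  set.seed(123)
  expect_identical(rnorm(1), before) # generator call left the stream alone

  r1 <- genReplicates(0.3, 0.05, 5, seed = 9)
  r2 <- genReplicates(0.3, 0.05, 5, seed = 9)
  expect_identical(replicateValues(r1$replicates),
                   replicateValues(r2$replicates))
  expect_false(identical(replicateValues(r1$replicates),
                         replicateValues(genReplicates(0.3, 0.05, 5,
                                                       seed = 10)$replicates)))
})

test_that("zero-mutation plants appear verbatim at their positions", {
  tr <- genGenome(2000, skewAmplitude = 0.2, seed = 1,
                  planted = list(list(pattern = "GTTACATTGTAAC", pos = 100,
                                      n_mut = 0)))
  txt <- as.character(genomeSeq(tr$genome))
  expect_identical(substr(txt, 101, 113), "GTTACATTGTAAC")
  expect_identical(tr$planted_sites$realized_seq, "GTTACATTGTAAC")
})

test_that("mutated plants record a reconstructable realized sequence", {
  tr <- genGenome(5000, skewAmplitude = 0.2, seed = 21,
                  planted = list(list(pattern = "GTTACNNNGTAAC", pos = 2000,
                                      n_mut = 2)))
  txt <- as.character(genomeSeq(tr$genome))
  s <- tr$planted_sites
  expect_identical(substr(txt, s$position + 1, s$position + 13),
                   s$realized_seq)
  expect_identical(s$n_mutations, 2L)
})

test_that("overlapping plants and bad parameters are rejected", {
  p <- list(list(pattern = "GTTACATTGTAAC", pos = 100, n_mut = 0),
            list(pattern = "GTTACATTGTAAC", pos = 105, n_mut = 0))
  expect_error(genGenome(2000, planted = p), "overlap")
  expect_error(genGenome(500), ">= 1000")
  expect_error(genGenome(2000, skewAmplitude = 0), "0, 1")
  expect_error(genGenome(2000, skewAmplitude = 1.5), "0, 1")
})

test_that("replichore base composition matches the requested skew", {
  tr <- genGenome(60000, skewAmplitude = 0.4, seed = 2)
  txt <- strsplit(as.character(genomeSeq(tr$genome)), "")[[1]]
  lead <- txt[seq_len(30000)] # ori at 0, ter at 30000
  sk <- (sum(lead == "G") - sum(lead == "C")) /
    (sum(lead == "G") + sum(lead == "C"))
  expect_equal(sk, 0.4, tolerance = 0.05)
})

test_that("lane profiles compose background, bands and noise as declared", {
  flat <- genLaneProfile(NULL, backgroundCoefficients = 5, noiseSd = 0,
                         lengthPx = 200, seed = 1)
  expect_equal(laneIntensities(flat$profile), rep(5, 200))

  one <- genLaneProfile(data.frame(center = 100, width = 6, area = 100),
                        backgroundCoefficients = 0, noiseSd = 0,
                        lengthPx = 200, seed = 1)
  y <- laneIntensities(one$profile)
  expect_equal(sum(y), 100, tolerance = 0.5) # unit-spaced quadrature

  expect_error(genLaneProfile(data.frame(center = 100, width = 6,
                                         area = -1), 0, 0, 200, 1),
               ">= 0")
  expect_error(genLaneProfile(data.frame(center = 300, width = 6,
                                         area = 1), 0, 0, 200, 1),
               "lengthPx")
})

test_that("titration truths follow the equilibrium curve exactly at zero noise", {
  tr <- genTitration(50, 0.1, 0.9, proteinConcs = c(0, 5, 50, 500),
                     dnaTotal = 2, noiseSd = 0)
  y <- titrationResponses(tr$series)
  expect_equal(y[1], 0.1) # baseline at zero protein
  f <- equilibriumBoundFraction(c(0, 5, 50, 500), 2, 50)
  expect_equal(y, 0.1 + 0.8 * f, tolerance = 1e-12)
  huge <- genTitration(50, 0.1, 0.9, proteinConcs = 1e9, noiseSd = 0)
  expect_equal(titrationResponses(huge$series), 0.9, tolerance = 1e-6)
})

test_that("helix scenes subtend the requested angle by construction", {
  for (ang in c(0, 30, 90)) {
    tr <- genHelixScene(ang, 10)
    dotp <- sum(tr$true_axes[1, ] * tr$true_axes[2, ])
    expect_equal(acos(pmin(abs(dotp), 1)) * 180 / pi, ang, tolerance = 1e-9)
  }
  expect_error(genHelixScene(60, 7), ">= 8")
  expect_error(genHelixScene(120, 10), "0, 90")
})

test_that("replicate generator matches its truth and posterior recovery is consistent", {
  zero <- genReplicates(0.3, 0, 5, seed = 1)
  expect_equal(replicateValues(zero$replicates), rep(0.3, 5))
  expect_error(genReplicates(0.3, 0.1, 1), ">= 2")

  big <- genReplicates(0.3, 0.02, 1000, seed = 4)
  ci <- posteriorMuCI(big$replicates)
  expect_lt(abs(posteriorMean(ci) - 0.3), 0.005)
})

test_that("FASTA round trip preserves sequence and topology", {
  tr <- genGenome(1500, skewAmplitude = 0.3, seed = 5)
  f <- tempfile(fileext = ".fasta")
  writeFasta(tr$genome, f)
  back <- readFasta(f)
  expect_identical(as.character(genomeSeq(back)),
                   as.character(genomeSeq(tr$genome)))
  expect_true(isCircular(back))

  # header token and case normalisation
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">g circular=true", "acgt"), f2)
  g <- readFasta(f2)
  expect_identical(as.character(genomeSeq(g)), "ACGT")
  expect_true(isCircular(g))

  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">g", "ACGN"), f3)
  expect_error(readFasta(f3), "position.*4")

  f4 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), f4)
  expect_error(readFasta(f4), "single-record")
})
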