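test_that("editDistance matches its definition on worked examples", {
  expect_identical(editDistance("GTGAC", "GTGAC"), 0L)
  expect_identical(editDistance("ACGT", ""), 4L)
  # the consensus matS vs the P. thracensis candidate site differ by 2 edits
  expect_identical(editDistance("GTGACATTGTCAC", "GTTACATTGTAAC"), 2L)
  expect_error(editDistance("ACGX", "ACGT"), "invalid character")
  expect_identical(editDistance("ACGT", "AGGT", method = "hamming"), 1L)
  expect_error(editDistance("ACGT", "ACG", method = "hamming"), "equal-length")
})

test_that("editDistance satisfies metric axioms and agrees with adist", {
  set.seed(11)
  for (i in 1:30) {
    a <- random_dna(sample(3:15, 1))
    b <- random_dna(sample(3:15, 1))
    cc <- random_dna(sample(3:15, 1))
    dab <- editDistance(a, b)
    expect_identical(dab, as.integer(oracle_levenshtein(a, b)))
    expect_identical(dab, editDistance(b, a))
    expect_identical(editDistance(a, a), 0L)
    expect_lte(editDistance(a, cc), dab + editDistance(b, cc))
  }
})

test_that("degenerate scanning finds N-wildcard matches", {
  g <- CircularGenome("toy", "AAGTTACATTGTAACAA")
  h <- scanMotifs(g, "GTTACNNNGTAAC", maxEdit = 0)
  expect_length(h, 1L)
  expect_identical(GenomicRanges::start(h) - 1L, 2L) # 0-based
  expect_identical(S4Vectors::mcols(h)$matched_seq, "GTTACATTGTAAC")

  none <- scanMotifs(g, "GTGACATTGTCAC", maxEdit = 0)
  expect_length(none, 0L)
})

test_that("edit-mode scanning reports minimum distances per locus", {
  g <- CircularGenome("toy", "AAGTTACATTGTAACAA")
  h <- scanMotifs(g, "GTGACATTGTCAC", maxEdit = 2)
  expect_length(h, 1L)
  expect_identical(GenomicRanges::start(h) - 1L, 2L)
  expect_identical(S4Vectors::mcols(h)$edit_distance, 2L)
})

test_that("edit scan equals brute-force window oracle on random genomes", {
  set.seed(23)
  for (rep in 1:4) {
    txt <- random_dna(1500)
    # plant two imperfect copies so hits exist
    pat <- "GTTACATTGTAAC"
    substr(txt, 301, 313) <- "GTTACATTGTAAC"
    substr(txt, 901, 913) <- "GTAACATTGTAAC"
    g <- CircularGenome("r", txt)
    for (k in 0:2) {
      got <- scanMotifs(g, pat, maxEdit = k, bothStrands = FALSE,
                        collapseOverlaps = FALSE)
      want <- oracle_edit_scan(txt, pat, k)
      expect_setequal(GenomicRanges::start(got) - 1L, want$start)
      got_d <- S4Vectors::mcols(got)$edit_distance[
        order(GenomicRanges::start(got))]
      expect_identical(as.integer(got_d), as.integer(want$dist))
    }
  }
})

test_that("max_edit 0 with N-free pattern equals exact substring search", {
  set.seed(5)
  txt <- random_dna(2000)
  g <- CircularGenome("r", txt)
  pat <- substr(txt, 1201, 1212)
  got <- scanMotifs(g, pat, maxEdit = 0, bothStrands = FALSE)
  want <- oracle_degenerate_scan(txt, pat)
  expect_setequal(GenomicRanges::start(got) - 1L, want)
})

test_that("degenerate scan equals brute force including N positions", {
  set.seed(6)
  txt <- random_dna(1200)
  substr(txt, 101, 113) <- "GTTACGGGGTAAC"
  substr(txt, 501, 513) <- "GTTACTTTGTAAC"
  g <- CircularGenome("r", txt)
  got <- scanMotifs(g, "GTTACNNNGTAAC", maxEdit = 0)
  want <- oracle_degenerate_scan(txt, "GTTACNNNGTAAC")
  expect_setequal(GenomicRanges::start(got) - 1L, want)
})

test_that("circular genomes are scanned across the origin", {
  # site split across the origin: last 6 bases + first 7 bases
  site <- "GTTACATTGTAAC"
  txt <- paste0(substr(site, 7, 13), strrep("A", 50), substr(site, 1, 6))
  g <- CircularGenome("c", txt, circular = TRUE)
  h <- scanMotifs(g, site, maxEdit = 0)
  expect_length(h, 1L)
  expect_identical(GenomicRanges::start(h) - 1L, nchar(txt) - 6L)
  # linear topology must not find it
  expect_length(scanMotifs(CircularGenome("l", txt), site, maxEdit = 0), 0L)
})

test_that("palindromic degenerate patterns give one forward hit per locus, covariant with reverse complement", {
  set.seed(9)
  txt <- random_dna(800)
  substr(txt, 201, 213) <- "GTTACGCAGTAAC"
  g <- CircularGenome("p", txt)
  pat <- "GTTACNNNGTAAC" # palindromic under N self-complementarity
  h <- scanMotifs(g, pat)
  expect_true(all(as.character(GenomicRanges::strand(h)) == "+"))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(txt, "")[[1]]),
                                     collapse = ""))
  h_rc <- scanMotifs(CircularGenome("p_rc", rc), pat)
  L <- nchar(txt); m <- nchar(pat)
  mapped <- L - (GenomicRanges::start(h_rc) - 1L) - m
  expect_setequal(GenomicRanges::start(h) - 1L, mapped)
})

test_that("planted sites within the edit budget are always recovered", {
  pat <- "GTTACATTGTAAC"
  for (seed in 1:5) {
    n_mut <- seed %% 3 # 0..2
    tr <- genGenome(20000, skewAmplitude = 0.2, seed = seed,
                    planted = list(list(pattern = pat, pos = 5000,
                                        n_mut = n_mut),
                                   list(pattern = pat, pos = 15000,
                                        n_mut = n_mut)))
    h <- scanMotifs(tr$genome, pat, maxEdit = 2)
    starts <- GenomicRanges::start(h) - 1L
    for (p in tr$planted_sites$position)
      expect_true(any(abs(starts - p) <= 2),
                  label = sprintf("seed %d pos %d recovered", seed, p))
  }
})

test_that("circularDistance handles wrap-around and degenerate cases", {
  expect_identical(circularDistance(0, 5, 10), 5)
  expect_identical(circularDistance(1, 9, 10), 2)
  expect_identical(circularDistance(3, 3, 10), 0)
  expect_error(circularDistance(0, 1, 0), "positive")
  expect_error(circularDistance(0, 12, 10), "0, length")
})

test_that("rankSiteFamilies orders families by median terminus distance", {
  L <- 100000
  ter <- 50000
  fam <- list(X = c(ter - 100, ter + 300, ter - 500) %% L,
              Y = (ter + 50000) %% L)
  r <- rankSiteFamilies(fam, ter, L)
  expect_identical(r$family_pattern, c("X", "Y"))
  expect_identical(r$median_ter_distance, c(300, 50000))
  expect_identical(r$rank, 1:2)

  single <- rankSiteFamilies(list(Z = c(10, 20)), 0, 1000)
  expect_identical(single$rank, 1L)

  tie <- rankSiteFamilies(list(B = 100, A = 900), 0, 1000)
  expect_identical(tie$family_pattern, c("A", "B")) # equal medians: lexicographic
})

test_that("globalIdentity matches hand-enumerated alignments", {
  expect_equal(globalIdentity("ACGT", "ACGT"), 100)
  expect_equal(globalIdentity("ACGT", "ACGA"), 75)
  expect_equal(globalIdentity("ACGTT", "ACGT"), 80) # 4 matches / 5 columns
  expect_error(globalIdentity("", "ACGT"), "non-empty")
  # protein alphabet works too
  expect_equal(globalIdentity("MSTIEER", "MSTIEER"), 100)
  expect_lt(globalIdentity("MSTIEER", "MSTLEER"), 100)
})
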