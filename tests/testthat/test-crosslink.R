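two_site_template <- function(p_head = 0.29, p_hinge = 0.62) {
  ComplexTemplate(
    data.frame(chain_id = c("MukB_kappa", "MukB_nu"), type = "MukB",
               reporter = TRUE, stringsAsFactors = FALSE),
    data.frame(name = c("head", "hinge"),
               chain_a = "MukB_kappa", chain_b = "MukB_nu",
               pos_a = c(0.02, 0.5), pos_b = c(0.02, 0.5),
               efficiency = c(p_head, p_hinge), stringsAsFactors = FALSE))
}

random_template <- function(n_chains, n_sites) {
  chains <- data.frame(chain_id = paste0("c", seq_len(n_chains)),
                       type = c("R", rep("S", n_chains - 1)),
                       reporter = c(TRUE, rep(FALSE, n_chains - 1)),
                       stringsAsFactors = FALSE)
  ends <- t(replicate(n_sites, sample(chains$chain_id, 2)))
  ComplexTemplate(chains, data.frame(
    name = paste0("s", seq_len(n_sites)),
    chain_a = ends[, 1], chain_b = ends[, 2],
    pos_a = runif(n_sites), pos_b = runif(n_sites),
    efficiency = runif(n_sites), stringsAsFactors = FALSE))
}

test_that("single-site enumeration yields the two outcomes", {
  tm <- ComplexTemplate(
    data.frame(chain_id = c("a", "b"), type = "P", reporter = c(TRUE, FALSE)),
    data.frame(name = "s", chain_a = "a", chain_b = "b", pos_a = 0.5,
               pos_b = 0.5, efficiency = 0.5))
  oc <- speciesOutcomes(enumerateSpecies(tm))
  expect_identical(nrow(oc), 2L)
  expect_equal(sort(oc$probability), c(0.5, 0.5))
})

test_that("head/hinge depletion arithmetic matches the independence model", {
  oc <- speciesOutcomes(enumerateSpecies(two_site_template()))
  head_only <- oc$probability[vapply(oc$formed_sites, function(s)
    setequal(s, "head"), logical(1))]
  expect_equal(head_only, 0.29 * (1 - 0.62), tolerance = 1e-12) # 0.1102
  expect_equal(sum(oc$probability), 1, tolerance = 1e-12)
})

test_that("species marginals equal site efficiencies on random templates", {
  set.seed(77)
  for (i in 1:5) {
    tm <- random_template(sample(3:5, 1), sample(2:6, 1))
    oc <- speciesOutcomes(enumerateSpecies(tm))
    expect_identical(nrow(oc), as.integer(2^nrow(templateSites(tm))))
    expect_equal(sum(oc$probability), 1, tolerance = 1e-12)
    for (s in templateSites(tm)$name) {
      marg <- sum(oc$probability[vapply(oc$formed_sites, function(f)
        s %in% f, logical(1))])
      expect_equal(marg, templateSites(tm)$efficiency[
        templateSites(tm)$name == s], tolerance = 1e-12)
    }
  }
})

test_that("degenerate efficiencies 0 and 1 prune outcomes", {
  tm <- mukbefTemplate(c(head = 0, hinge = 1))
  oc <- speciesOutcomes(enumerateSpecies(tm))
  nonzero <- oc[oc$probability > 0, ]
  expect_true(all(vapply(nonzero$formed_sites, function(f)
    !"head" %in% f, logical(1))))
  expect_true(all(vapply(nonzero$formed_sites, function(f)
    "hinge" %in% f, logical(1))))
})

test_that("compartment circles are detected and named", {
  tm <- mukbefTemplate()
  expect_identical(findCovalentCircles(tm, c("cap", "neck", "hinge")), "ring")
  expect_identical(findCovalentCircles(tm, c("cap", "neck", "head")), "clamp")
  expect_identical(findCovalentCircles(tm, c("head", "hinge")), "frame")
  expect_identical(findCovalentCircles(tm, c("cap", "neck")), character(0))
  expect_identical(findCovalentCircles(tm, character(0)), character(0))
  # all four sites: all three named cycles coexist in the cycle space
  expect_setequal(findCovalentCircles(tm, c("cap", "neck", "hinge", "head")),
                  c("ring", "clamp", "frame"))
  expect_error(findCovalentCircles(tm, "nope"), "unknown site")
})

test_that("circle detection equals igraph-based subset enumeration", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:6) {
    tm <- random_template(sample(3:5, 1), sample(2:6, 1))
    st <- templateSites(tm)
    got <- findCovalentCircles(tm, st$name)
    want <- oracle_cycles(st$chain_a, st$chain_b, st$name)
    want_names <- sort(unique(vapply(want, paste, character(1),
                                     collapse = "+")))
    expect_identical(got, want_names)
  }
})

test_that("raising the hinge efficiency depletes the head-only species", {
  probs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(ph) {
    oc <- speciesOutcomes(enumerateSpecies(two_site_template(0.29, ph)))
    oc$probability[vapply(oc$formed_sites, function(s)
      setequal(s, "head"), logical(1))]
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("inferSiteEfficiency reproduces the depletion reading", {
  expect_equal(inferSiteEfficiency(0.29, 0.12), 1 - 0.12 / 0.29,
               tolerance = 1e-12) # ~0.586, reported as a ~60% reduction
  expect_equal(inferSiteEfficiency(0.5, 0.5), 0)
  expect_equal(inferSiteEfficiency(0.5, 0.25), 0.5)
  expect_error(inferSiteEfficiency(0.2, 0.3), "exceeds")
  expect_error(inferSiteEfficiency(0, 0), "0, 1")
})

test_that("template JSON round trip preserves the model", {
  tm <- mukbefTemplate()
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(chains = templateChains(tm),
                            sites = templateSites(tm),
                            compartments = tm@compartments),
                       path, auto_unbox = TRUE, digits = NA)
  tm2 <- readTemplateJSON(path)
  expect_equal(templateSites(tm2), templateSites(tm))
  expect_identical(findCovalentCircles(tm2, c("cap", "neck", "hinge")),
                   "ring")
})
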