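test_that("star genealogies put every tip at the stated TMRCA", {
  cfg <- simulationConfig(nSamples = 5, genealogy = "star",
                          tmrcaYears = 10000, seed = 1L)
  tr <- simulateGenealogy(cfg)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$edge.length, rep(10000, 5))
  expect_equal(attr(tr, "tmrcaYears"), 10000)
})

test_that("the same seed reproduces the same dataset", {
  ref <- mtRef()
  cfg <- simulationConfig(nSamples = 10, genealogy = "kingman_coalescent",
                          tmrcaYears = 6000, seed = 12L)
  a <- simulateDataset(cfg, ref)
  b <- simulateDataset(cfg, ref)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$variantSets, b$variantSets)
  expect_identical(a$genealogy$edge.length, b$genealogy$edge.length)
})

test_that("coalescent branch lengths match the Kingman expectation", {
  ## E[total length] = 2 * scale * sum_{k=2..n} 1/(k-1)
  n <- 6L; scale <- 1000
  tot <- vapply(seq_len(1000), function(s) {
    cfg <- simulationConfig(nSamples = n, genealogy = "kingman_coalescent",
                            tmrcaYears = scale, seed = s)
    sum(simulateGenealogy(cfg)$edge.length)
  }, 0)
  expected <- 2 * scale * sum(1 / (seq(2, n) - 1))
  mcse <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * mcse)
})

test_that("a vanishing mutation rate leaves every sequence at the root state", {
  ref <- mtRef()
  slowClock <- new("MtClock", id = "complete_genome",
                   yearsPerMutation = 1e12)
  cfg <- simulationConfig(nSamples = 6, genealogy = "star",
                          tmrcaYears = 10000, clock = slowClock, seed = 2L)
  sim <- simulateDataset(cfg, ref)
  expect_true(all(lengths(sim$variantSets) == 0L))
  expect_true(all(sim$sequences == refSequence(ref)))
  tr <- buildMPTree(sim$profiles)
  expect_equal(computeRho(tr)$rho, 0)
})

test_that("per-tip event counts follow the Poisson mean T over rate", {
  ref <- mtRef()
  nrep <- 200L
  means <- vapply(seq_len(nrep), function(s) {
    cfg <- simulationConfig(nSamples = 50, genealogy = "star",
                            tmrcaYears = 7248, seed = 500L + s)
    mean(simulateDataset(cfg, ref, sequences = FALSE)$eventsPerTip)
  }, 0)
  mcse <- sd(means) / sqrt(nrep)
  expect_lt(abs(mean(means) - 2.0), 3 * mcse)
})

test_that("scoring evolved sequences recovers the true variant sets exactly", {
  ref <- mtRef()
  cfg <- simulationConfig(nSamples = 20, genealogy = "kingman_coalescent",
                          tmrcaYears = 20000, seed = 33L)
  sim <- simulateDataset(cfg, ref)
  scored <- lapply(sim$sequences, function(s) scoreSequence(s, ref)$name)
  for (id in names(scored))
    expect_setequal(scored[[id]], sim$variantSets[[id]])
})

test_that("the truth tree replays to the simulated profiles", {
  ref <- mtRef()
  cfg <- simulationConfig(nSamples = 12, genealogy = "kingman_coalescent",
                          tmrcaYears = 15000, seed = 44L)
  sim <- simulateDataset(cfg, ref, sequences = FALSE)
  expect_true(validObject(sim$trueTree))  # validity replays all events
  sampled <- which(nodeMultiplicity(sim$trueTree) > 0L)
  for (i in sampled) {
    id <- nodeSamples(sim$trueTree)[[i]]
    expect_setequal(nodeHaplotypes(sim$trueTree)[[i]],
                    sim$variantSets[[id]])
  }
})

test_that("finite-sites mode produces genuine homoplasy for the search to flag", {
  ref <- mtRef()
  hot <- setNames(rep(5000, 8), as.character(c(150, 152, 16189, 16311,
                                               16093, 16223, 195, 204)))
  cfg <- simulationConfig(nSamples = 10, genealogy = "kingman_coalescent",
                          tmrcaYears = 40000, seed = 55L,
                          infiniteSites = FALSE, hotspotMultipliers = hot)
  sim <- simulateDataset(cfg, ref, sequences = FALSE)
  ev <- do.call(rbind, sim$trueTree@events)
  expect_gt(sum(ev$parallel) + sum(ev$back), 0L)
})

test_that("simulating on a nomenclature scaffold keeps samples inside the clade", {
  ref <- mtRef()
  nom <- mtNom()
  motif <- cumulativeMotif(nom, "C5c")
  cfg <- simulationConfig(nSamples = 15, genealogy = "kingman_coalescent",
                          tmrcaYears = 8000, seed = 66L,
                          rootHaplotype = motif)
  sim <- simulateDataset(cfg, ref)
  for (v in sim$variantSets) {
    lab <- assignHaplogroup(v, nom)$label
    expect_true("C5c" %in% ancestorLabels(nom, lab))
  }
})

test_that("synonymous-clock simulations only touch synonymous sites", {
  ref <- mtRef()
  cfg <- simulationConfig(nSamples = 10, genealogy = "star",
                          tmrcaYears = 40000, clock = synonymousClock(),
                          seed = 77L)
  sim <- simulateDataset(cfg, ref, sequences = FALSE)
  vars <- unique(unlist(sim$variantSets))
  expect_gt(length(vars), 0L)
  parsed <- parseVariants(vars, ref)
  cls <- classifySubstitution(ref, parsed$np, parsed$alt)$category
  expect_true(all(cls == "synonymous"))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulationConfig(0), "nSamples")
  expect_error(simulationConfig(5, tmrcaYears = -1), "tmrcaYears")
  expect_error(simulationConfig(5, populations = data.frame(
    name = "A", region = "other", weight = 0.5)), "sum to 1")
  expect_error(simulationConfig(5, genealogy = "fixed_tree"), "phylo")
})
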