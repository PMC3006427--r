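test_that("star clades follow the closed-form rho and sigma", {
  ## four tips, two private mutations each
  tr <- buildMPTree(list(A = c("101", "102"), B = c("201", "202"),
                         C = c("301", "302"), D = c("401", "402")))
  r <- computeRho(tr)
  expect_equal(r$rho, 2)
  expect_equal(r$sigma, sqrt(2 / 4))
  expect_equal(r$n, 4L)
})

test_that("a single sample identical to the clade root has rho = sigma = 0", {
  tr <- buildMPTree(list(A = c("10", "20")), rootHaplotype = c("10", "20"))
  r <- computeRho(tr)
  expect_equal(r$rho, 0)
  expect_equal(r$sigma, 0)
})

test_that("the branch-structure sigma matches direct enumeration", {
  ## shared internal branch (1 event) above two tips with one further
  ## event each, plus one direct tip with one event:
  ## rho = (2+2+1)/3, sigma^2 = (1*2^2 + 1 + 1 + 1)/9
  tr <- buildMPTree(list(P = c("100", "200"), Q = c("100", "300"),
                         R = "400"))
  r <- computeRho(tr)
  expect_equal(r$rho, 5 / 3, tolerance = 1e-12)
  expect_equal(r$sigma^2, 7 / 9, tolerance = 1e-12)
})

test_that("sigma reduces to sqrt(rho/n) on random star clades", {
  set.seed(17)
  for (i in 1:40) {
    k <- sample(3:8, 1)
    counts <- sample(0:4, k, replace = TRUE)
    pool <- sample(setdiff(100:16000, 3107L), sum(counts))
    off <- 0L
    profiles <- lapply(seq_len(k), function(j) {
      v <- as.character(pool[seq_len(counts[j]) + off])
      off <<- off + counts[j]
      v
    })
    names(profiles) <- paste0("S", seq_len(k))
    tr <- buildMPTree(profiles)
    r <- computeRho(tr)
    expect_equal(r$rho, mean(counts), tolerance = 1e-12)
    expect_equal(r$sigma, sqrt(r$rho / k), tolerance = 1e-12,
                 label = sprintf("star case %d", i))
  }
})

test_that("rho is invariant to collapsing identical tips into multiplicities", {
  ## three copies of one haplotype, one of another
  profiles <- list(A1 = "100", A2 = "100", A3 = "100", B = c("200", "300"))
  tr <- buildMPTree(profiles)
  r <- computeRho(tr)
  expect_equal(r$n, 4L)
  expect_equal(r$rho, (1 * 3 + 2 * 1) / 4)
  ## the three identical samples occupy one node
  expect_equal(sum(nodeMultiplicity(tr) > 0), 2L)
})

test_that("clock conversion is linear, floored at zero, and validated", {
  cg <- completeGenomeClock()
  expect_equal(rhoToAge(1, 0, cg)$age_years, 3624)
  expect_equal(rhoToAge(1, 0, synonymousClock())$age_years, 7884)
  z <- rhoToAge(0, 0, cg)
  expect_equal(c(z$age_years, z$ci_low_years, z$ci_high_years), c(0, 0, 0))
  ## arithmetic consistency with the headline haplogroup C age
  expect_equal(rhoToAge(7.552, 0, cg)$age_years / 1000, 27.37, tolerance = 1e-3)
  ## linearity
  r1 <- 0.73; r2 <- 1.91
  expect_equal(rhoToAge(r1 + r2, 0, cg)$age_years,
               rhoToAge(r1, 0, cg)$age_years + rhoToAge(r2, 0, cg)$age_years)
  expect_error(rhoToAge(-1, 0, cg), "non-negative")
  ## CI ordering invariant
  a <- rhoToAge(2.5, 0.8, cg)
  expect_true(a$ci_low_years <= a$age_years &&
                a$age_years <= a$ci_high_years)
})

test_that("the synonymous clock counts only synonymous substitutions", {
  ref <- mtRef()
  syn <- synonymousChanges(ref)
  synName <- with(syn[match(FALSE, duplicated(syn$np)), ],
                  ifelse(mclass == "transition", as.character(np),
                         paste0(np, alt)))
  ## one synonymous coding change, one control-region transition, and one
  ## nonsynonymous change
  nonsyn <- NULL
  for (np in 5905:5950) {
    alt <- setdiff(c("A", "C", "G", "T"), refBase(ref, np))[1]
    if (classifySubstitution(ref, np, alt)$category == "nonsynonymous") {
      nonsyn <- ifelse(alt == c(A = "G", G = "A", C = "T", T = "C")[refBase(ref, np)],
                       as.character(np), paste0(np, alt))
      break
    }
  }
  profiles <- list(A = c(synName, "16093", nonsyn))
  tr <- buildMPTree(profiles)
  rAll <- computeRho(tr, completeGenomeClock())
  rSyn <- computeRho(tr, synonymousClock(), ref = ref)
  expect_equal(rAll$rho, 3)
  expect_equal(rSyn$rho, 1)
  ## indels never count under either clock
  tr2 <- buildMPTree(list(A = c(synName, "2232.1A", "5000del")))
  expect_equal(computeRho(tr2, completeGenomeClock())$rho, 1)
  expect_error(computeRho(tr2, synonymousClock()), "reference")
})

test_that("an empty clade cannot be dated", {
  tr <- buildMPTree(list(A = "100"))
  expect_error(computeRho(tr, clade = 99L), "not a node")
})

test_that("rho recovers the simulated TMRCA on star genealogies", {
  ref <- mtRef()
  nrep <- 60L
  T <- 10000
  ages <- vapply(seq_len(nrep), function(s) {
    cfg <- simulationConfig(nSamples = 100, genealogy = "star",
                            tmrcaYears = T, seed = 3000L + s)
    sim <- simulateDataset(cfg, ref, sequences = FALSE)
    tr <- buildMPTree(sim$profiles)
    computeRho(tr)$rho * 3624
  }, 0)
  mcse <- sd(ages) / sqrt(nrep)
  expect_lt(abs(mean(ages) - T), 3 * mcse)
})

test_that("clade tables date every labelled clade under both clocks", {
  ref <- mtRef()
  nom <- mtNom()
  motif <- cumulativeMotif(nom, "C5c")
  profiles <- list(
    S1 = c(motif, "16291", "5426"),
    S2 = c(motif, "16291"),
    S3 = c(motif, "16234", "9545"),
    S4 = c(motif, "16234"),
    S5 = motif)
  tr <- buildMPTree(profiles, rootHaplotype = motif)
  ages <- dateAllClades(tr, nom, ref)
  expect_true(all(c("C5c", "C5c1", "C5c2") %in% ages$clade))
  expect_setequal(unique(ages$clock), c("complete_genome", "synonymous"))
  ## two clocks per clade, invariants on each row
  expect_equal(nrow(ages), 2L * length(unique(ages$clade)))
  expect_true(all(ages$ci_low_ky <= ages$age_ky + 1e-9 &
                    ages$age_ky <= ages$ci_high_ky + 1e-9))
  expect_true(all(ages$rho >= 0 & ages$sigma >= 0))
  ## the C5c clade contains all five samples
  expect_equal(unique(ages$n[ages$clade == "C5c"]), 5L)
  ## whole-clade rho weighs the subclades correctly under the star bound:
  ## rho(C5c) >= weighted mean of subclade rhos minus the connecting events
  cg <- ages[ages$clock == "complete_genome", ]
  expect_gte(cg$rho[cg$clade == "C5c"],
             (2 * cg$rho[cg$clade == "C5c1"] +
              2 * cg$rho[cg$clade == "C5c2"]) / 5 - 1)
})
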