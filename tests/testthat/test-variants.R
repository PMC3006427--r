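test_that("scoring an identical sequence yields no variants", {
  ref <- mtRef()
  expect_equal(nrow(scoreSequence(refSequence(ref), ref)), 0L)
})

test_that("canonical naming distinguishes transitions, transversions and indels", {
  ref <- mtRef()
  q <- refSequence(ref)
  substr(q, 16093, 16093) <- altFor(ref, 16093L, "transition")
  substr(q, 16518, 16518) <- altFor(ref, 16518L, "transversion")
  v <- scoreSequence(q, ref, insertions = c("2232" = "A"))
  expect_setequal(v$name, c("16093",
                            paste0("16518", altFor(ref, 16518L, "transversion")),
                            "2232.1A"))
  expect_equal(v$mclass[match("16093", v$name)], "transition")
  expect_equal(v$mclass[v$np == 16518], "transversion")
  expect_equal(v$mclass[v$name == "2232.1A"], "insertion")
  ## deletions are reported per deleted position
  q2 <- refSequence(ref)
  substr(q2, 16166, 16166) <- "-"
  expect_equal(scoreSequence(q2, ref)$name, "16166del")
})

test_that("ambiguity handling: N skipped with warning, others fatal", {
  ref <- mtRef()
  q <- refSequence(ref)
  substr(q, 5000, 5000) <- "N"
  expect_warning(v <- scoreSequence(q, ref), "N position")
  expect_equal(nrow(v), 0L)
  substr(q, 5000, 5000) <- "R"
  expect_error(scoreSequence(q, ref), "ambiguity")
})

test_that("variant naming is injective over (np, alt, class)", {
  ref <- mtRef()
  set.seed(11)
  np <- sample(setdiff(1:16569, 3107L), 500L)
  alt <- vapply(np, function(p)
    sample(setdiff(c("A", "C", "G", "T"), refBase(ref, p)), 1L), "")
  nm <- vapply(seq_along(np), function(i) {
    v <- scoreSequence(`substr<-`(refSequence(ref), np[i], np[i], alt[i]),
                       ref)
    v$name
  }, "")
  expect_equal(anyDuplicated(nm), 0L)
  ## and parsing inverts naming
  parsed <- parseVariants(nm, ref)
  expect_equal(parsed$np, np)
  expect_equal(parsed$alt, alt)
})

test_that("score -> apply round-trips substitutions and indels exactly", {
  ref <- mtRef()
  set.seed(21)
  for (i in 1:25) {
    np <- sample(setdiff(1:16569, 3107L), 12L)
    q <- refSequence(ref)
    for (p in np[1:8])
      substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        refBase(ref, p)), 1L)
    for (p in np[9:10]) substr(q, p, p) <- "-"
    ins <- setNames(c("A", "GT"), as.character(np[11:12]))
    v <- scoreSequence(q, ref, insertions = ins)
    ## reconstruction equals the degapped query with insertions included
    rebuilt <- applyVariants(v, ref)
    manual <- strsplit(q, "")[[1]]
    pieces <- ifelse(manual == "-", "", manual)
    for (a in names(ins))
      pieces[as.integer(a)] <- paste0(pieces[as.integer(a)], ins[[a]])
    expect_equal(rebuilt, paste(pieces, collapse = ""))
    ## and re-scoring the positional form reproduces the variant table
    v2 <- scoreSequence(q, ref, insertions = ins)
    expect_identical(v, v2)
  }
})

test_that("exclusion filters drop indels and transversions only inside the windows", {
  ref <- mtRef()
  ## the motif examples: a transversion at 16182, an insertion at 309
  expect_equal(applyExclusionFilters(c("16182C")), character())
  expect_equal(applyExclusionFilters(c("309.1C")), character())
  expect_equal(applyExclusionFilters(c("16189", "7694")),
               c("16189", "7694"))
  ## table form agrees
  q <- refSequence(ref)
  substr(q, 16189, 16189) <- altFor(ref, 16189L, "transition")
  v <- scoreSequence(q, ref, insertions = c("309" = "C", "5899" = "C"))
  filt <- applyExclusionFilters(v)
  expect_setequal(filt$name, c("16189", "5899.1C"))
  ## genome-wide indel exclusion is available behind the flag
  expect_equal(applyExclusionFilters(v, excludeIndelsEverywhere = TRUE)$name,
               "16189")
})

test_that("exclusion filtering is idempotent and never removes a transition", {
  set.seed(31)
  for (i in 1:40) {
    nm <- c(randomTransitionNames(8),
            paste0(sample(c(300:320, 16175:16198), 4), "del"),
            paste0(sample(c(305:314, 16181:16192), 2), ".1C"))
    once <- applyExclusionFilters(nm)
    expect_identical(applyExclusionFilters(once), once)
    expect_lte(length(once), length(nm))
    ## every transition survives
    expect_true(all(nm[grepl("^[0-9]+$", nm)] %in% once))
  }
})

test_that("profile tables round-trip through the variant-list format", {
  prof <- HaploProfiles(c("S1", "S2", "S3"),
                        list(c("16093", "16189"), character(), "2232.1A"),
                        population = c("PopA", "PopA", "PopB"),
                        region = "eastern_asia",
                        coverage = c("hvs1", "complete", "complete"))
  f <- tempfile(fileext = ".tsv")
  writeProfileTable(prof, f)
  back <- readProfileTable(f)
  expect_equal(sampleInfo(back), sampleInfo(prof))
  expect_equal(unname(profileVariants(back)), prof@variants)
})

test_that("hvs1 profiles may only carry control-region HVS1 variants", {
  expect_error(HaploProfiles("S1", list(c("16093", "7694")),
                             coverage = "hvs1"),
               "outside")
})

test_that("minimal VCF export writes anchor-based records", {
  ref <- mtRef()
  prof <- HaploProfiles(c("A", "B"),
                        list(c("16093", "2232.1A"), c("16093", "5000del")))
  f <- tempfile(fileext = ".vcf")
  writeVariantVCF(prof, ref, f)
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- read.delim(text = lines[!grepl("^##", lines)], check.names = FALSE)
  expect_equal(nrow(body), 3L)
  ins <- body[body$ID == "2232.1A", ]
  expect_equal(nchar(ins$ALT), 2L)  # anchor base + inserted A
  del <- body[body$ID == "5000del", ]
  expect_equal(as.integer(del$POS), 4999L)
  expect_equal(body$A[body$ID == "16093"], 1L)
  expect_equal(body$B[body$ID == "5000del"], 1L)
})

test_that("near-rCRS sequences align back into rCRS coordinates", {
  ref <- mtRef()
  ## sequences whose length differs from rCRS force a real alignment;
  ## exact-length ungapped input is diffed positionally by contract
  q <- refSequence(ref)
  substr(q, 9000, 9000) <- altFor(ref, 9000L)
  chars <- strsplit(q, "")[[1]]
  subName <- scoreSequence(q, ref)$name
  ## a 16,568-bp sequence with one base deleted
  aln <- alignToReference(paste(chars[-12000L], collapse = ""), ref)
  v <- scoreSequence(aln$query, ref, insertions = aln$insertions)
  expect_setequal(v$name, c(subName, "12000del"))
  ## a 16,570-bp sequence with one base inserted
  aln2 <- alignToReference(paste(append(chars, "A", after = 6999L),
                                 collapse = ""), ref)
  v2 <- scoreSequence(aln2$query, ref, insertions = aln2$insertions)
  expect_true(subName %in% v2$name)
  ins <- v2[v2$mclass == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$alt, "A")
  expect_lte(ins$np, 7000L)  # left-aligned anchor
})
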