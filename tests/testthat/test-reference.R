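test_that("the reference loads with rCRS geometry and placeholder handling", {
  ref <- mtRef()
  expect_s4_class(ref, "MtReference")
  expect_equal(nchar(refSequence(ref)), 16569L)
  expect_equal(refBase(ref, 3107L), "N")
  ## the placeholder position is never a variant site
  expect_error(classifySubstitution(ref, 3107L, "A"), "placeholder")
  expect_error(parseVariants("3107", ref), "placeholder")
})

test_that("a truncated reference is rejected as not rCRS", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">trunc", strrep("ACGT", 4142)), fa)  # 16,568 bp
  expect_error(loadReference(fa), "not rCRS")
})

test_that("an unannotated same-strand protein overlap is rejected", {
  an <- refFeatures(mtRef())
  an$end[an$name == "ND2"] <- an$start[an$name == "CO1"] + 5L
  anFile <- tempfile(fileext = ".tsv")
  write.table(an, anFile, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    loadReference(annotationFile = anFile), "overlap")
})

test_that("region classification follows the annotation", {
  ref <- mtRef()
  ## 16360 (a D5a3 marker) lies in the control region
  expect_equal(classifySubstitution(ref, 16360L,
                                    altFor(ref, 16360L))$category,
               "control_region")
  ## 10454 (part of the C5c motif) falls in a tRNA gene
  r <- classifySubstitution(ref, 10454L, altFor(ref, 10454L))
  expect_equal(r$category, "tRNA")
  ## 7694 (the C5c1a marker) is protein-coding: synonymous or not is
  ## decided by translating the affected codon
  r2 <- classifySubstitution(ref, 7694L, altFor(ref, 7694L))
  expect_true(r2$category %in% c("synonymous", "nonsynonymous"))
  expect_equal(r2$gene, "CO2")
  ## an alt equal to the reference base is not a variant
  expect_error(classifySubstitution(ref, 1000L, refBase(ref, 1000L)),
               "not a variant")
})

## independent oracle: translate the whole gene before and after the
## substitution (coding strand), then compare amino-acid sequences
oracleClassify <- function(ref, np, alt) {
  f <- refFeatures(ref)
  cover <- f[f$start <= np & f$end >= np, , drop = FALSE]
  prot <- cover[cover$type == "protein", , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  code <- Biostrings::getGeneticCode("2")
  if (nrow(prot)) {
    cats <- vapply(seq_len(nrow(prot)), function(k) {
      g <- prot[k, ]
      s <- substring(refSequence(ref), g$start, g$end)
      q <- s
      substr(q, np - g$start + 1L, np - g$start + 1L) <- alt
      if (g$strand == "light") {
        rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]),
                                collapse = "")
        s <- rc(s); q <- rc(q)
      }
      nC <- nchar(s) %/% 3L
      off <- if (g$strand == "heavy") np - g$start else g$end - np
      if (off %/% 3L + 1L > nC) return("coding_terminal")
      tri <- function(x) substring(x, 3 * seq_len(nC) - 2, 3 * seq_len(nC))
      identicalAA <- identical(unname(code[tri(s)]), unname(code[tri(q)]))
      if (identicalAA) "synonymous" else "nonsynonymous"
    }, "")
    if (any(cats == "nonsynonymous")) return("nonsynonymous")
    if (any(cats == "synonymous")) return("synonymous")
    return("coding_terminal")
  }
  if (any(cover$type == "tRNA")) return("tRNA")
  if (any(cover$type == "rRNA")) return("rRNA")
  if (any(cover$type == "control")) return("control_region")
  "intergenic"
}

test_that("classification agrees with whole-gene translation on random sites", {
  ref <- mtRef()
  set.seed(104)
  nps <- sample(setdiff(1:16569, 3107L), 1000L, replace = TRUE)
  for (np in nps) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refBase(ref, np)), 1L)
    expect_equal(classifySubstitution(ref, np, alt)$category,
                 oracleClassify(ref, np, alt),
                 label = sprintf("np %d -> %s", np, alt))
  }
})

test_that("light-strand protein substitutions are read on the coding strand", {
  ref <- mtRef()
  f <- refFeatures(ref)
  nd6 <- f[f$name == "ND6", ]
  expect_equal(nd6$strand, "light")
  ## manual reverse-complement translation of one codon
  np <- nd6$start + 10L  # inside ND6, past the (coding-strand) start codon
  alt <- altFor(ref, np)
  got <- classifySubstitution(ref, np, alt)
  expect_equal(got$category, oracleClassify(ref, np, alt))
  expect_equal(got$gene, "ND6")
})

test_that("overlapping protein genes report every per-gene call", {
  ref <- mtRef()
  f <- refFeatures(ref)
  a8 <- f[f$name == "ATP8", ]; a6 <- f[f$name == "ATP6", ]
  np <- a6$start + 4L  # inside the ATP8/ATP6 overlap
  expect_lte(np, a8$end)
  r <- classifySubstitution(ref, np, altFor(ref, np))
  det <- r$details[[1]]
  expect_setequal(det$gene, c("ATP8", "ATP6"))
  ## severity rule: nonsynonymous wins if any gene is nonsynonymous
  if (any(det$category == "nonsynonymous"))
    expect_equal(r$category, "nonsynonymous")
})

test_that("the synonymous-change catalogue is deterministic and self-consistent", {
  ref <- mtRef()
  sc1 <- synonymousChanges(ref)
  sc2 <- synonymousChanges(ref)
  expect_identical(sc1, sc2)
  expect_gt(nrow(sc1), 1000L)
  ## spot-check 50 pairs against the classifier
  set.seed(7)
  idx <- sample(nrow(sc1), 50L)
  cls <- classifySubstitution(ref, sc1$np[idx], sc1$alt[idx])$category
  expect_true(all(cls == "synonymous"))
})
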