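## Reference genome: loading, accessors, functional classification of
## substitutions under the vertebrate mitochondrial genetic code.

## stop codons of the vertebrate mitochondrial code
MT_STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")

mtGeneticCode <- function() Biostrings::getGeneticCode("2")

#' Load a reference mitochondrial genome
#'
#' Reads a FASTA sequence and a tab-delimited annotation table into an
#' [MtReference-class] object. The sequence must be exactly 16,569 bp (rCRS
#' numbering) with the placeholder base `N` at np 3107. Overlapping
#' same-strand protein genes are accepted only for the two known overlaps
#' (ATP8/ATP6 and ND4L/ND4); any other same-strand protein overlap is
#' treated as an annotation error.
#'
#' @param fastaFile Path to a single-record FASTA file.
#' @param annotationFile Path to a tab-delimited table with columns
#'   `name`, `start`, `end`, `strand`, `type`. Defaults to the bundled
#'   standard human mtDNA annotation.
#' @return An [MtReference-class] object.
#' @examples
#' ref <- loadReference()
#' ref
#' @export
loadReference <- function(fastaFile = system.file("extdata",
                            "synthetic_rcrs.fasta", package = "mitophylo"),
                          annotationFile = system.file("extdata",
                            "mt_annotation.tsv", package = "mitophylo")) {
  seqs <- Biostrings::readDNAStringSet(fastaFile)
  if (length(seqs) != 1L)
    stop("reference FASTA must contain exactly one record")
  if (length(seqs[[1]]) != MT_LENGTH)
    stop(sprintf("not rCRS: sequence length %d, expected %d",
                 length(seqs[[1]]), MT_LENGTH))
  feats <- read.delim(annotationFile, stringsAsFactors = FALSE)
  feats$start <- as.integer(feats$start)
  feats$end <- as.integer(feats$end)
  checkProteinOverlaps(feats)
  new("MtReference", sequence = seqs[[1]], features = feats)
}

checkProteinOverlaps <- function(feats) {
  p <- feats[feats$type == "protein", , drop = FALSE]
  if (nrow(p) < 2L) return(invisible(TRUE))
  allowed <- list(c("ATP8", "ATP6"), c("ND4L", "ND4"), c("ATP6", "CO3"))
  for (i in seq_len(nrow(p) - 1L)) for (j in (i + 1L):nrow(p)) {
    if (p$strand[i] != p$strand[j]) next
    if (p$start[j] <= p$end[i] && p$start[i] <= p$end[j]) {
      pair <- sort(c(p$name[i], p$name[j]))
      ok <- any(vapply(allowed, function(a) identical(sort(a), pair), TRUE))
      if (!ok)
        stop(sprintf("unexpected same-strand protein overlap: %s/%s",
                     p$name[i], p$name[j]))
    }
  }
  invisible(TRUE)
}

#' Accessors for MtReference
#'
#' `refSequence()` returns the reference sequence as a single character
#' string; `refFeatures()` the annotation table; `refBase()` the reference
#' base(s) at given rCRS position(s).
#'
#' @param ref An [MtReference-class] object.
#' @param np Integer vector of rCRS positions (1-based).
#' @return `refSequence()`: a character scalar; `refFeatures()`: a
#'   `data.frame`; `refBase()`: a character vector of bases.
#' @examples
#' ref <- loadReference()
#' refBase(ref, c(3107L, 16093L))
#' @export
refSequence <- function(ref) as.character(ref@sequence)

#' @rdname refSequence
#' @export
refFeatures <- function(ref) ref@features

#' @rdname refSequence
#' @export
refBase <- function(ref, np) {
  stopifnot(all(np >= 1L & np <= MT_LENGTH))
  refCharVec(ref)[np]
}

## features covering one position
featuresAt <- function(ref, np) {
  f <- ref@features
  f[f$start <= np & f$end >= np, , drop = FALSE]
}

## per-gene coding-strand context of a genomic position inside a protein gene
codonContext <- function(seqChars, feat, np) {
  len <- feat$end - feat$start + 1L
  off <- if (feat$strand == "heavy") np - feat$start else feat$end - np
  codonIndex <- off %/% 3L + 1L
  codonPos <- off %% 3L + 1L
  nComplete <- len %/% 3L
  if (codonIndex > nComplete)
    return(list(terminal = TRUE, codonIndex = codonIndex, codonPos = codonPos))
  if (feat$strand == "heavy") {
    gpos <- feat$start + (codonIndex - 1L) * 3L + 0:2
    codon <- seqChars[gpos]
  } else {
    gpos <- feat$end - (codonIndex - 1L) * 3L - 0:2
    codon <- unname(BASE_COMPLEMENT[seqChars[gpos]])
  }
  list(terminal = FALSE, codonIndex = codonIndex, codonPos = codonPos,
       codon = codon)
}

#' Classify a substitution functionally
#'
#' Determines, for each substitution relative to the reference, whether it is
#' synonymous or nonsynonymous (protein genes, translated on the coding
#' strand with the vertebrate mitochondrial genetic code; the one
#' light-strand protein gene is read on the reverse complement), or falls in
#' a tRNA, rRNA, control-region or intergenic position. At overlapping
#' protein genes every covering gene is evaluated and the most severe
#' category is reported (nonsynonymous over synonymous); substitutions in an
#' incomplete terminal codon (completed post-transcriptionally by
#' polyadenylation) are reported as `coding_terminal` and never count as
#' synonymous.
#'
#' @param ref An [MtReference-class] object.
#' @param np Integer vector of rCRS positions.
#' @param alt Character vector of alternative bases (recycled against `np`).
#' @return A `data.frame` with columns `np`, `alt`, `category` (one of
#'   `synonymous`, `nonsynonymous`, `coding_terminal`, `tRNA`, `rRNA`,
#'   `control_region`, `intergenic`), `gene`, `codon_index`,
#'   `codon_position`, plus a list-column `details` with the per-gene calls
#'   at overlapping protein genes.
#' @examples
#' ref <- loadReference()
#' classifySubstitution(ref, 16360L, setdiff(c("A","C","G","T"),
#'                                           refBase(ref, 16360L))[1])
#' @export
classifySubstitution <- function(ref, np, alt) {
  np <- as.integer(np)
  alt <- toupper(as.character(alt))
  n <- max(length(np), length(alt))
  np <- rep_len(np, n)
  alt <- rep_len(alt, n)
  if (any(np < 1L | np > MT_LENGTH))
    stop("np out of rCRS range 1..16569")
  if (any(np == PLACEHOLDER_NP))
    stop(sprintf("np %d is the rCRS placeholder position, not a variant site",
                 PLACEHOLDER_NP))
  if (!all(alt %in% DNA_BASES))
    stop("alt must be one of A, C, G, T")
  seqChars <- refCharVec(ref)
  if (any(alt == seqChars[np]))
    stop("not a variant: alt equals the reference base")
  code <- mtGeneticCode()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- classifyOne(ref, seqChars, code, np[i], alt[i])
  }
  res <- do.call(rbind, lapply(out, `[[`, "row"))
  res$details <- lapply(out, `[[`, "details")
  res
}

classifyOne <- function(ref, seqChars, code, np, alt) {
  feats <- featuresAt(ref, np)
  prot <- feats[feats$type == "protein", , drop = FALSE]
  blank <- data.frame(np = np, alt = alt, category = NA_character_,
                      gene = "", codon_index = NA_integer_,
                      codon_position = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(prot)) {
    per <- lapply(seq_len(nrow(prot)), function(k) {
      feat <- prot[k, ]
      ctx <- codonContext(seqChars, feat, np)
      if (ctx$terminal)
        return(data.frame(gene = feat$name, category = "coding_terminal",
                          codon_index = ctx$codonIndex,
                          codon_position = ctx$codonPos,
                          stringsAsFactors = FALSE))
      codon <- ctx$codon
      altCodon <- codon
      altCodon[ctx$codonPos] <- if (feat$strand == "heavy") alt else
        unname(BASE_COMPLEMENT[alt])
      aaRef <- code[[paste(codon, collapse = "")]]
      aaAlt <- code[[paste(altCodon, collapse = "")]]
      data.frame(gene = feat$name,
                 category = if (identical(aaRef, aaAlt)) "synonymous"
                            else "nonsynonymous",
                 codon_index = ctx$codonIndex, codon_position = ctx$codonPos,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    ## severity-first: nonsynonymous > synonymous > coding_terminal
    pick <- if (any(per$category == "nonsynonymous"))
      which(per$category == "nonsynonymous")[1]
    else if (any(per$category == "synonymous"))
      which(per$category == "synonymous")[1]
    else 1L
    blank$category <- per$category[pick]
    blank$gene <- per$gene[pick]
    if (blank$category %in% c("synonymous", "nonsynonymous")) {
      blank$codon_index <- per$codon_index[pick]
      blank$codon_position <- per$codon_position[pick]
    }
    return(list(row = blank, details = per))
  }
  ## non-protein precedence: tRNA > rRNA > control > intergenic
  cat <- if (any(feats$type == "tRNA")) "tRNA"
    else if (any(feats$type == "rRNA")) "rRNA"
    else if (any(feats$type == "control")) "control_region"
    else "intergenic"
  blank$category <- cat
  if (cat != "intergenic")
    blank$gene <- feats$name[match(sub("_region", "", cat), feats$type)]
  list(row = blank, details = NULL)
}

#' Enumerate all possible synonymous single-base changes
#'
#' Lists every (position, alternative base) pair whose substitution is
#' classified synonymous, honouring the severity rule at overlapping protein
#' genes (a change must be synonymous in *every* covering protein gene) and
#' excluding incomplete terminal codons. Used by the synonymous clock and by
#' the sequence simulator.
#'
#' @param ref An [MtReference-class] object.
#' @return A `data.frame` with columns `np`, `alt` and `mclass`
#'   (`"transition"` or `"transversion"`).
#' @export
synonymousChanges <- function(ref) {
  seqChars <- refCharVec(ref)
  code <- mtGeneticCode()
  prot <- ref@features[ref@features$type == "protein", , drop = FALSE]
  rows <- vector("list", nrow(prot))
  for (g in seq_len(nrow(prot))) {
    feat <- prot[g, ]
    len <- feat$end - feat$start + 1L
    gpos <- if (feat$strand == "heavy") feat$start:feat$end else
      feat$end:feat$start
    coding <- if (feat$strand == "heavy") seqChars[gpos] else
      unname(BASE_COMPLEMENT[seqChars[gpos]])
    nComplete <- len %/% 3L
    nCoding <- nComplete * 3L
    codIdx <- rep(seq_len(nComplete), each = 3L)
    codPos <- rep(1:3, nComplete)
    cstart <- (seq_len(nComplete) - 1L) * 3L
    codons <- paste0(coding[cstart + 1L], coding[cstart + 2L],
                     coding[cstart + 3L])
    aaRef <- unname(code[codons])
    acc <- vector("list", 3L)
    for (b in seq_along(DNA_BASES)) {
      altCoding <- DNA_BASES[b]
      sel <- which(coding[seq_len(nCoding)] != altCoding)
      if (!length(sel)) next
      mutCodon <- codons[codIdx[sel]]
      substr(mutCodon, codPos[sel], codPos[sel]) <- altCoding
      syn <- unname(code[mutCodon]) == aaRef[codIdx[sel]]
      altGenomic <- if (feat$strand == "heavy") altCoding else
        unname(BASE_COMPLEMENT[altCoding])
      acc[[b]] <- data.frame(np = gpos[sel], alt = altGenomic, syn = syn,
                             stringsAsFactors = FALSE)
    }
    ## terminal positions (incomplete stop codon) are never synonymous
    term <- if (nCoding < len) gpos[(nCoding + 1L):len] else integer()
    rows[[g]] <- list(calls = do.call(rbind, acc), terminal = term)
  }
  calls <- do.call(rbind, lapply(rows, `[[`, "calls"))
  terminal <- unique(unlist(lapply(rows, `[[`, "terminal")))
  calls <- calls[!calls$np %in% terminal, , drop = FALSE]
  key <- paste(calls$np, calls$alt)
  allSyn <- tapply(calls$syn, key, all)
  keep <- !duplicated(key) & allSyn[key]
  out <- calls[keep, c("np", "alt")]
  out <- out[order(out$np, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  ## a pair can also fall in the terminal codon of an overlapping gene only
  ## via the `terminal` exclusion above; classify transition vs transversion
  refB <- seqChars[out$np]
  out$mclass <- ifelse(unname(TRANSITION_PARTNER[refB]) == out$alt,
                       "transition", "transversion")
  out
}

#' Generate the bundled synthetic reference sequence
#'
#' The package cannot redistribute the rCRS sequence itself, so it bundles a
#' synthetic stand-in: a deterministic random sequence of the exact rCRS
#' length with human-mtDNA-like base composition, the placeholder `N` at np
#' 3107, and repaired protein reading frames (start codon `ATG`, no internal
#' stop codons where reading frames do not overlap, complete or incomplete
#' stop codons as annotated). All coordinate-dependent logic (annotation,
#' codon arithmetic, motif positions) is exact; only the base identities are
#' synthetic.
#'
#' @param annotation Annotation `data.frame` (as in [refFeatures()]).
#' @param seed Integer seed; the default reproduces the bundled FASTA.
#' @return A character scalar of length 16,569.
#' @export
syntheticReferenceSequence <- function(annotation = read.delim(
                                         system.file("extdata",
                                           "mt_annotation.tsv",
                                           package = "mitophylo")),
                                       seed = 20100L) {
  withLocalSeed(seed, {
    s <- sample(DNA_BASES, MT_LENGTH, replace = TRUE,
                prob = c(0.31, 0.31, 0.13, 0.25))
    s[PLACEHOLDER_NP] <- "N"
    locked <- rep(FALSE, MT_LENGTH)
    prot <- annotation[annotation$type == "protein", , drop = FALSE]
    setCodingBase <- function(np, strand, base) {
      if (locked[np]) return(invisible(FALSE))
      s[np] <<- if (strand == "heavy") base else unname(BASE_COMPLEMENT[base])
      locked[np] <<- TRUE
      invisible(TRUE)
    }
    for (g in seq_len(nrow(prot))) {
      feat <- prot[g, ]
      len <- feat$end - feat$start + 1L
      gpos <- if (feat$strand == "heavy") feat$start:feat$end else
        feat$end:feat$start
      start <- c("A", "T", "G")
      for (k in 1:3) setCodingBase(gpos[k], feat$strand, start[k])
      rem <- len %% 3L
      if (rem == 0L) {
        stop_ <- c("T", "A", "A")
        for (k in 1:3) setCodingBase(gpos[len - 3L + k], feat$strand, stop_[k])
      } else {
        partial <- c("T", "A")[seq_len(rem)]
        for (k in seq_len(rem))
          setCodingBase(gpos[len - rem + k], feat$strand, partial[k])
      }
    }
    ## iterative repair of internal stop codons (overlaps can reintroduce)
    for (pass in 1:6) {
      changed <- FALSE
      for (g in seq_len(nrow(prot))) {
        feat <- prot[g, ]
        len <- feat$end - feat$start + 1L
        gpos <- if (feat$strand == "heavy") feat$start:feat$end else
          feat$end:feat$start
        nComplete <- len %/% 3L
        lastInternal <- if (len %% 3L == 0L) nComplete - 1L else nComplete
        for (ci in 2:lastInternal) {
          idx <- (ci - 1L) * 3L + 1:3
          codon <- if (feat$strand == "heavy") s[gpos[idx]] else
            unname(BASE_COMPLEMENT[s[gpos[idx]]])
          if (paste(codon, collapse = "") %in% MT_STOP_CODONS) {
            ## demote to a sense codon via the third, else second, base
            np3 <- gpos[idx[3]]; np2 <- gpos[idx[2]]
            if (!locked[np3]) {
              s[np3] <- if (feat$strand == "heavy") "C" else "G"
              changed <- TRUE
            } else if (!locked[np2]) {
              s[np2] <- if (feat$strand == "heavy") "C" else "G"
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
    paste(s, collapse = "")
  })
}
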