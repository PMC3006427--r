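## Variant scoring against the rCRS coordinate system: canonical naming,
## sequence diffing, site-exclusion filters, and profile table I/O.

mutationClass <- function(refBase, altBase) {
  ifelse(unname(TRANSITION_PARTNER[refBase]) == altBase,
         "transition", "transversion")
}

## canonical name for a substitution: bare np for transitions, np+allele
## for transversions (e.g. "16518T")
substitutionName <- function(np, refBase, altBase) {
  ifelse(mutationClass(refBase, altBase) == "transition",
         as.character(np), paste0(np, altBase))
}

emptyVariantTable <- function() {
  data.frame(name = character(), np = integer(), ref = character(),
             alt = character(), mclass = character(), stringsAsFactors = FALSE)
}

#' Parse canonical variant names
#'
#' Converts canonical variant names into a variant table. Transitions are
#' written as the bare position (`"16093"`), transversions carry the derived
#' allele (`"16518T"`), deletions end in `del` (`"16166del"`), and
#' insertions use sub-index notation (`"2232.1A"` = first inserted base
#' after np 2232). A positional name with an allele suffix that equals the
#' transition partner of the reference base is still classed as a
#' transition: the mutation class always follows the bases, not the
#' spelling.
#'
#' @param names Character vector of canonical variant names.
#' @param ref An [MtReference-class] object (supplies reference alleles).
#' @return A `data.frame` with columns `name`, `np`, `ref`, `alt`, `mclass`.
#' @examples
#' ref <- loadReference()
#' parseVariants(c("16093", "309.1C", "16166del"), ref)
#' @export
parseVariants <- function(names, ref) {
  if (!length(names)) return(emptyVariantTable())
  seqChars <- refCharVec(ref)
  one <- function(nm) {
    if (grepl("^[0-9]+$", nm)) {
      np <- as.integer(nm)
      checkNp(np)
      rb <- seqChars[np]
      if (rb == "N")
        stop(sprintf("cannot express a transition at placeholder np %d", np))
      data.frame(name = nm, np = np, ref = rb,
                 alt = unname(TRANSITION_PARTNER[rb]),
                 mclass = "transition", stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+[ACGT]$", nm)) {
      np <- as.integer(sub("[ACGT]$", "", nm))
      checkNp(np)
      alt <- substr(nm, nchar(nm), nchar(nm))
      rb <- seqChars[np]
      if (alt == rb)
        stop(sprintf("'%s': allele equals the reference base", nm))
      data.frame(name = substitutionName(np, rb, alt), np = np, ref = rb,
                 alt = alt, mclass = mutationClass(rb, alt),
                 stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+del$", nm)) {
      np <- as.integer(sub("del$", "", nm))
      checkNp(np)
      data.frame(name = nm, np = np, ref = seqChars[np], alt = "",
                 mclass = "deletion", stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", nm)) {
      np <- as.integer(sub("\\..*$", "", nm))
      checkNp(np)
      alt <- substr(nm, nchar(nm), nchar(nm))
      data.frame(name = nm, np = np, ref = "", alt = alt,
                 mclass = "insertion", stringsAsFactors = FALSE)
    } else {
      stop(sprintf("cannot parse variant name '%s'", nm))
    }
  }
  out <- do.call(rbind, lapply(names, one))
  rownames(out) <- NULL
  out
}

checkNp <- function(np) {
  if (is.na(np) || np < 1L || np > MT_LENGTH)
    stop("np out of rCRS range 1..16569")
  if (np == PLACEHOLDER_NP)
    stop(sprintf("np %d is the rCRS placeholder position, not a variant site",
                 PLACEHOLDER_NP))
  invisible(np)
}

#' Score an aligned sequence against the reference
#'
#' Computes the rCRS-relative variant set of a query that is already in
#' rCRS coordinates: a string of exactly 16,569 characters in which `-`
#' marks a deleted position, plus an optional insertion track. Positions
#' holding `N` are skipped with a warning; any other ambiguity code is an
#' error. The rCRS placeholder position 3107 is never reported.
#'
#' @param query Character scalar (or [Biostrings::DNAString]) of length
#'   16,569 aligned to rCRS coordinates, `-` marking deletions. Use
#'   [alignToReference()] first for an unaligned near-rCRS sequence.
#' @param ref An [MtReference-class] object.
#' @param insertions Named character vector: names are anchor positions
#'   (`"2232"`), values the inserted bases (`"A"`, `"CC"`, ...). Inserted
#'   bases are named `np.1X`, `np.2X`, ... after the anchor.
#' @return A variant table as in [parseVariants()], ordered by position.
#' @examples
#' ref <- loadReference()
#' q <- refSequence(ref)
#' substr(q, 100, 100) <- setdiff(c("A","G"), refBase(ref, 100L))[1]
#' scoreSequence(q, ref)
#' @export
scoreSequence <- function(query, ref, insertions = NULL) {
  query <- toupper(as.character(query))
  if (nchar(query) != MT_LENGTH)
    stop(sprintf(paste0("query length %d is not the rCRS length %d; ",
                        "align it first (see alignToReference)"),
                 nchar(query), MT_LENGTH))
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  bad <- !q %in% c(DNA_BASES, "N", "-")
  if (any(bad))
    stop(sprintf("ambiguity codes other than N are not supported: '%s'",
                 paste(unique(q[bad]), collapse = "', '")))
  if (any(q == "N" & seq_along(q) != PLACEHOLDER_NP))
    warning(sprintf("%d N position(s) skipped",
                    sum(q == "N" & seq_along(q) != PLACEHOLDER_NP)))
  r <- refCharVec(ref)
  use <- q != "N" & seq_along(q) != PLACEHOLDER_NP
  subs <- which(use & q != r & q != "-")
  dels <- which(use & q == "-")
  out <- list()
  if (length(subs))
    out$sub <- data.frame(name = substitutionName(subs, r[subs], q[subs]),
                          np = subs, ref = r[subs], alt = q[subs],
                          mclass = mutationClass(r[subs], q[subs]),
                          stringsAsFactors = FALSE)
  if (length(dels))
    out$del <- data.frame(name = paste0(dels, "del"), np = dels,
                          ref = r[dels], alt = "", mclass = "deletion",
                          stringsAsFactors = FALSE)
  if (length(insertions)) {
    anchors <- as.integer(names(insertions))
    if (any(is.na(anchors) | anchors < 1L | anchors > MT_LENGTH))
      stop("insertion anchors must be rCRS positions")
    ins <- lapply(seq_along(anchors), function(i) {
      bases <- strsplit(toupper(insertions[[i]]), "", fixed = TRUE)[[1]]
      if (!all(bases %in% DNA_BASES))
        stop("inserted bases must be A, C, G or T")
      data.frame(name = paste0(anchors[i], ".", seq_along(bases), bases),
                 np = anchors[i], ref = "", alt = bases,
                 mclass = "insertion", stringsAsFactors = FALSE)
    })
    out$ins <- do.call(rbind, ins)
  }
  if (!length(out)) return(emptyVariantTable())
  res <- do.call(rbind, out)
  res <- res[order(res$np, res$mclass != "insertion", res$name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reconstruct a sample sequence from its variant set
#'
#' Applies a variant table (or canonical names) to the reference, returning
#' the sample's actual sequence: substituted bases replaced, deleted
#' positions removed, inserted bases added after their anchors. Inverse of
#' [scoreSequence()] up to alignment coordinates.
#'
#' @param variants A variant table (as from [scoreSequence()]) or a
#'   character vector of canonical names.
#' @param ref An [MtReference-class] object.
#' @return A character scalar: the reconstructed sequence.
#' @export
applyVariants <- function(variants, ref) {
  if (is.character(variants)) variants <- parseVariants(variants, ref)
  s <- refCharVec(ref)
  keep <- rep(TRUE, MT_LENGTH)
  insAfter <- vector("list", MT_LENGTH)
  if (nrow(variants)) {
    if (anyDuplicated(paste(variants$np, variants$alt, variants$mclass)))
      stop("duplicate (np, alt) in variant set")
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      switch(v$mclass,
        transition = ,
        transversion = { s[v$np] <- v$alt },
        deletion = { keep[v$np] <- FALSE },
        insertion = {
          k <- as.integer(sub("^[0-9]+\\.([0-9]+)[ACGT]$", "\\1", v$name))
          insAfter[[v$np]][k] <- v$alt
        },
        stop("unknown mutation class"))
    }
  }
  pieces <- character(MT_LENGTH)
  pieces[keep] <- s[keep]
  hasIns <- which(lengths(insAfter) > 0L)
  for (np in hasIns)
    pieces[np] <- paste0(pieces[np], paste(insAfter[[np]], collapse = ""))
  paste(pieces, collapse = "")
}

#' Exclude unstable sites from phylogenetic analysis
#'
#' Removes every insertion, deletion and transversion whose position (the
#' anchor position for insertions) falls in the two mutational hotspot
#' windows nps 16180--16193 and 303--315 (the poly-C tracts); transitions in
#' those windows are retained, and everything outside passes through
#' unchanged. With `excludeIndelsEverywhere = TRUE` point indels are dropped
#' genome-wide instead of only inside the windows. Idempotent.
#'
#' @param variants A variant table (as from [scoreSequence()]) or a
#'   character vector of canonical names (classes are then inferred from
#'   the naming convention).
#' @param excludeIndelsEverywhere Drop insertions and deletions at every
#'   position, not only inside the two windows. Default `FALSE`.
#' @return Filtered object of the same type as the input.
#' @examples
#' applyExclusionFilters(c("16182C", "309.1C", "16189", "7694"))
#' @export
applyExclusionFilters <- function(variants, excludeIndelsEverywhere = FALSE) {
  if (is.character(variants)) {
    np <- as.integer(sub("^([0-9]+).*$", "\\1", variants))
    mclass <- ifelse(grepl("^[0-9]+$", variants), "transition",
              ifelse(grepl("del$", variants), "deletion",
              ifelse(grepl("\\.", variants), "insertion", "transversion")))
  } else {
    np <- variants$np
    mclass <- variants$mclass
  }
  indel <- mclass %in% c("insertion", "deletion")
  targeted <- indel | mclass == "transversion"
  drop <- (targeted & inExclusionWindow(np)) | (indel & excludeIndelsEverywhere)
  if (is.character(variants)) variants[!drop] else {
    out <- variants[!drop, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
}

#' Align a near-rCRS sequence into rCRS coordinates
#'
#' Global pairwise alignment of an unaligned, close-to-reference sequence
#' onto the reference, returning the positional (gapped) query string and
#' the insertion track that [scoreSequence()] expects. Indels are
#' left-aligned (lowest possible np). This is a convenience for sequences
#' a few edits away from rCRS, not a general aligner.
#'
#' @param seq Character scalar (or [Biostrings::DNAString]): the sample
#'   sequence.
#' @param ref An [MtReference-class] object.
#' @return A list with elements `query` (length-16,569 string with `-` at
#'   deleted positions) and `insertions` (named character vector of
#'   insertion tracks, possibly empty).
#' @export
alignToReference <- function(seq, ref) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == MT_LENGTH && !grepl("-", seq, fixed = TRUE))
    return(list(query = seq, insertions = setNames(character(), character())))
  subMat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq),
    subject = ref@sequence, type = "global",
    substitutionMatrix = subMat, gapOpening = 6, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- character(MT_LENGTH)
  insAfter <- vector("list", MT_LENGTH + 1L)
  np <- 0L
  for (i in seq_along(s)) {
    if (s[i] == "-") {
      insAfter[[np + 1L]] <- c(insAfter[[np + 1L]], p[i])
    } else {
      np <- np + 1L
      qpos[np] <- p[i]
    }
  }
  ## left-align insertions through homopolymer runs
  r <- refCharVec(ref)
  ins <- setNames(character(), character())
  for (a in which(lengths(insAfter) > 0L)) {
    bases <- insAfter[[a]]
    anchor <- a - 1L  # stored at np+1; the insertion follows base `anchor`
    while (anchor >= 1L && qpos[anchor] != "-" &&
           r[anchor] == bases[length(bases)]) {
      bases <- c(bases[length(bases)], bases[-length(bases)])
      anchor <- anchor - 1L
    }
    if (anchor < 1L) anchor <- 1L
    key <- as.character(anchor)
    ins[key] <- paste0(paste(bases, collapse = ""),
                       if (key %in% names(ins)) ins[[key]] else "")
  }
  list(query = paste(qpos, collapse = ""), insertions = ins)
}
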