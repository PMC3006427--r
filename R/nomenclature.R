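## Haplogroup nomenclature: loading the clade-definition tree and assigning
## profiles to their most derived matching haplogroup.

#' Load a haplogroup nomenclature tree
#'
#' Reads a tab-delimited nomenclature file with columns `label`, `parent`
#' (empty for the root), `variants` (comma-separated defining variant
#' names, `.` for none), `negatives` (variants that must be absent, `.` for
#' none) and `status` (`defined` or `placeholder`). The bundled fixture
#' encodes the haplogroup C and D clades whose diagnostic motifs the source
#' data state explicitly (e.g. C5c = 10454-16093-16518T-16527, C4e =
#' 151-152-7307-15479 with absence of the 2232.1A insertion, D5a3 = 16360);
#' backbone clades whose full motifs are not stated carry empty defining
#' sets and are marked `placeholder`.
#'
#' @param file Path to the nomenclature file; defaults to the bundled
#'   haplogroup C/D fixture.
#' @return A [HaploNomenclature-class] object.
#' @examples
#' nom <- loadNomenclature()
#' definingVariants(nom, "C5c")
#' @export
loadNomenclature <- function(file = system.file("extdata",
                               "cd_nomenclature.tsv",
                               package = "mitophylo")) {
  d <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = NULL)
  need <- c("label", "parent", "variants", "negatives", "status")
  if (!all(need %in% names(d)))
    stop("nomenclature file must have columns ", paste(need, collapse = ", "))
  splitCol <- function(x) lapply(x, function(v)
    if (v %in% c("", ".")) character() else strsplit(v, ",", fixed = TRUE)[[1]])
  new("HaploNomenclature",
      nodes = data.frame(label = d$label, parent = d$parent,
                         status = d$status, stringsAsFactors = FALSE),
      defining = setNames(splitCol(d$variants), d$label),
      negative = setNames(splitCol(d$negatives), d$label))
}

#' Query a nomenclature tree
#'
#' `nodeLabels()` lists all haplogroup labels; `rootLabel()` the root;
#' `childLabels()` the children of a node; `nodeDepth()` the number of
#' edges from the root; `definingVariants()` and `negativeMarkers()` a
#' node's own markers; `cumulativeMotif()` the union of defining variants
#' along the root path (the full motif a member of the clade carries);
#' `cumulativeNegatives()` the union of negative markers along that path.
#'
#' @param tree A [HaploNomenclature-class] object.
#' @param label A haplogroup label.
#' @return Character vectors (or an integer for `nodeDepth()`).
#' @export
nodeLabels <- function(tree) tree@nodes$label

#' @rdname nodeLabels
#' @export
rootLabel <- function(tree) tree@nodes$label[tree@nodes$parent == ""]

#' @rdname nodeLabels
#' @export
childLabels <- function(tree, label) {
  tree@nodes$label[tree@nodes$parent == label]
}

checkLabel <- function(tree, label) {
  if (!label %in% tree@nodes$label)
    stop(sprintf("unknown haplogroup label '%s'", label))
  invisible(label)
}

rootPath <- function(tree, label) {
  checkLabel(tree, label)
  par <- setNames(tree@nodes$parent, tree@nodes$label)
  path <- character()
  cur <- label
  while (cur != "") {
    path <- c(cur, path)
    cur <- par[[cur]]
  }
  path
}

#' @rdname nodeLabels
#' @export
nodeDepth <- function(tree, label) length(rootPath(tree, label)) - 1L

#' @rdname nodeLabels
#' @export
ancestorLabels <- function(tree, label) rootPath(tree, label)

#' @rdname nodeLabels
#' @export
definingVariants <- function(tree, label) {
  checkLabel(tree, label)
  tree@defining[[label]]
}

#' @rdname nodeLabels
#' @export
negativeMarkers <- function(tree, label) {
  checkLabel(tree, label)
  tree@negative[[label]]
}

#' @rdname nodeLabels
#' @export
cumulativeMotif <- function(tree, label) {
  unique(unlist(tree@defining[rootPath(tree, label)], use.names = FALSE))
}

#' @rdname nodeLabels
#' @export
cumulativeNegatives <- function(tree, label) {
  unique(unlist(tree@negative[rootPath(tree, label)], use.names = FALSE))
}

variantNp <- function(names) as.integer(sub("^([0-9]+).*$", "\\1", names))

#' Assign a profile to its most derived matching haplogroup
#'
#' Walks the nomenclature tree from the root and returns the most derived
#' haplogroup whose cumulative motif is carried by the profile and whose
#' negative markers are absent. "Most derived" is measured by the number of
#' diagnostic markers matched; among equally good nodes on one lineage the
#' least committed (shallowest) is returned, and equally good nodes on
#' different lineages resolve to their most recent common ancestor with an
#' ambiguity flag. HVS1 profiles are matched only on markers inside the
#' HVS1 span (nps 16024--16383); markers outside it are ignored for such
#' profiles. If nothing beyond the root matches, the root label is returned
#' with `assigned = FALSE`.
#'
#' @param variants Character vector of canonical variant names (one
#'   profile), or a [HaploProfiles-class] object for
#'   `assignHaplogroups()`.
#' @param tree A [HaploNomenclature-class] object.
#' @param coverage `"complete"` or `"hvs1"`.
#' @param allowMissing Number of missing diagnostic markers tolerated along
#'   the whole root path (default 0: motif-exact matching).
#' @return `assignHaplogroup()`: a list with elements `label`, `assigned`,
#'   `ambiguous`, `matched`, `missing` (markers of the returned label's
#'   cumulative motif absent from the profile, non-empty only when
#'   `allowMissing > 0`), and `extra` (profile variants not used by the
#'   returned label's motif). `assignHaplogroups()`: a `data.frame` with
#'   one row per sample.
#' @examples
#' nom <- loadNomenclature()
#' assignHaplogroup(c("10454", "16093", "16518T", "16527", "16234"), nom)$label
#' @export
assignHaplogroup <- function(variants, tree,
                             coverage = c("complete", "hvs1"),
                             allowMissing = 0L) {
  coverage <- match.arg(coverage)
  variants <- unique(as.character(variants))
  restrict <- function(v) {
    if (coverage == "hvs1") v[inHVS1(variantNp(v))] else v
  }
  root <- rootLabel(tree)
  ## DFS accumulating missing-marker counts; a node is visited only if its
  ## whole root path matches within the tolerance
  hits <- list()
  visit <- function(label, missingSoFar, matchedSoFar) {
    need <- restrict(tree@defining[[label]])
    neg <- restrict(tree@negative[[label]])
    if (length(neg) && any(neg %in% variants)) return(invisible())
    miss <- setdiff(need, variants)
    missingSoFar <- missingSoFar + length(miss)
    if (missingSoFar > allowMissing) return(invisible())
    matchedSoFar <- matchedSoFar + length(need) - length(miss)
    hits[[length(hits) + 1L]] <<- list(label = label,
                                       matched = matchedSoFar,
                                       missing = missingSoFar)
    for (ch in childLabels(tree, label))
      visit(ch, missingSoFar, matchedSoFar)
  }
  visit(root, 0L, 0L)
  matched <- vapply(hits, `[[`, 0L, "matched")
  best <- which(matched == max(matched))
  cand <- vapply(hits[best], `[[`, "", "label")
  ambiguous <- FALSE
  if (length(cand) == 1L) {
    label <- cand
  } else {
    ## prefer the shallowest candidate if candidates lie on one lineage
    paths <- lapply(cand, rootPath, tree = tree)
    depths <- lengths(paths)
    shallow <- cand[which.min(depths)]
    onOneLineage <- all(vapply(paths, function(p) shallow %in% p, TRUE))
    if (onOneLineage) {
      label <- shallow
    } else {
      ## most recent common ancestor of all equally good candidates
      common <- Reduce(intersect, paths)
      label <- common[length(common)]
      ambiguous <- TRUE
    }
  }
  motif <- restrict(cumulativeMotif(tree, label))
  list(label = label,
       assigned = label != root,
       ambiguous = ambiguous,
       matched = intersect(motif, variants),
       missing = setdiff(motif, variants),
       extra = setdiff(variants, motif))
}

#' @rdname assignHaplogroup
#' @param x A [HaploProfiles-class] object.
#' @export
assignHaplogroups <- function(x, tree, allowMissing = 0L) {
  rows <- lapply(seq_len(nSamples(x)), function(i) {
    a <- assignHaplogroup(x@variants[[i]], tree,
                          coverage = x@info$coverage[i],
                          allowMissing = allowMissing)
    data.frame(sample_id = x@info$sample_id[i],
               population = x@info$population[i],
               region = x@info$region[i],
               coverage = x@info$coverage[i],
               haplogroup = a$label, assigned = a$assigned,
               ambiguous = a$ambiguous,
               n_matched = length(a$matched),
               n_missing = length(a$missing),
               n_extra = length(a$extra), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
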