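#' @importClassesFrom Biostrings DNAString
NULL

## ---------------------------------------------------------------------------
## MtReference
## ---------------------------------------------------------------------------

#' Reference mitochondrial genome in rCRS numbering
#'
#' Holds the 16,569-bp reference sequence (1-based, circular rCRS
#' coordinates) together with its feature annotation. Position 3107 carries
#' the historical placeholder base `N` and is never reported as a variant
#' site.
#'
#' @slot sequence A [Biostrings::DNAString] of length 16,569.
#' @slot features A `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (`"heavy"` or `"light"`) and `type` (`"protein"`, `"tRNA"`,
#'   `"rRNA"`, `"control"` or `"noncoding"`); coordinates are 1-based closed
#'   intervals.
#'
#' @seealso [loadReference()], [classifySubstitution()]
#' @exportClass MtReference
setClass("MtReference",
  representation(sequence = "DNAString", features = "data.frame")
)

setValidity("MtReference", function(object) {
  msg <- character()
  if (length(object@sequence) != MT_LENGTH)
    msg <- c(msg, sprintf("sequence length %d: not rCRS (expected %d)",
                          length(object@sequence), MT_LENGTH))
  else if (as.character(object@sequence[PLACEHOLDER_NP]) != "N")
    msg <- c(msg, sprintf("position %d must hold the rCRS placeholder base N",
                          PLACEHOLDER_NP))
  need <- c("name", "start", "end", "strand", "type")
  if (!all(need %in% names(object@features)))
    msg <- c(msg, paste("features must have columns",
                        paste(need, collapse = ", ")))
  else {
    f <- object@features
    if (any(f$start < 1L | f$end > MT_LENGTH | f$start > f$end))
      msg <- c(msg, "feature coordinates out of 1..16569 or reversed")
    if (!all(f$strand %in% c("heavy", "light")))
      msg <- c(msg, "feature strand must be 'heavy' or 'light'")
    if (!all(f$type %in% c("protein", "tRNA", "rRNA", "control", "noncoding")))
      msg <- c(msg, "unknown feature type")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MtReference-class Compact display.
#' @param object An `MtReference`.
#' @export
setMethod("show", "MtReference", function(object) {
  f <- object@features
  cat("MtReference (rCRS numbering), ", length(object@sequence), " bp\n",
      sep = "")
  cat("  features: ", nrow(f), " (",
      sum(f$type == "protein"), " protein, ",
      sum(f$type == "tRNA"), " tRNA, ",
      sum(f$type == "rRNA"), " rRNA)\n", sep = "")
})

## ---------------------------------------------------------------------------
## HaploNomenclature
## ---------------------------------------------------------------------------

#' Haplogroup nomenclature tree
#'
#' A rooted hierarchy of haplogroup labels. Each node carries the variants
#' that define it relative to its parent (its motif) and, optionally,
#' negative markers: variants that must be absent (e.g. the lack of an
#' adenine insertion at np 2232 distinguishing C4e from C4a'b'c).
#'
#' @slot nodes A `data.frame` with columns `label`, `parent` (empty string
#'   for the root) and `status` (`"defined"` if the motif is fully specified,
#'   `"placeholder"` if the defining variants are not encoded).
#' @slot defining Named list (by label) of character vectors of canonical
#'   variant names.
#' @slot negative Named list (by label) of variant names that must be absent.
#'
#' @seealso [loadNomenclature()], [assignHaplogroup()]
#' @exportClass HaploNomenclature
setClass("HaploNomenclature",
  representation(nodes = "data.frame", defining = "list", negative = "list")
)

setValidity("HaploNomenclature", function(object) {
  nd <- object@nodes
  msg <- character()
  if (anyDuplicated(nd$label))
    msg <- c(msg, "duplicate haplogroup labels")
  roots <- nd$label[nd$parent == ""]
  if (length(roots) != 1L)
    msg <- c(msg, "tree must have exactly one root")
  known <- c("", nd$label)
  if (!all(nd$parent %in% known))
    msg <- c(msg, "orphan parent label")
  if (any(nd$parent == nd$label))
    msg <- c(msg, "node cannot be its own parent")
  ## cycle check by walking to the root from every node
  if (!length(msg)) {
    par <- setNames(nd$parent, nd$label)
    for (lab in nd$label) {
      seen <- character()
      cur <- lab
      while (cur != "") {
        if (cur %in% seen) {
          msg <- c(msg, sprintf("cyclic parent links at '%s'", lab))
          break
        }
        seen <- c(seen, cur)
        cur <- par[[cur]]
      }
      if (length(msg)) break
    }
  }
  if (!all(nd$label %in% names(object@defining)))
    msg <- c(msg, "every node needs an entry in @defining")
  if (length(msg)) msg else TRUE
})

#' @describeIn HaploNomenclature-class Compact display.
#' @param object A `HaploNomenclature`.
#' @export
setMethod("show", "HaploNomenclature", function(object) {
  nd <- object@nodes
  cat("HaploNomenclature with ", nrow(nd), " haplogroups (root '",
      nd$label[nd$parent == ""], "'), ",
      sum(nd$status == "defined"), " with encoded motifs\n", sep = "")
})

## ---------------------------------------------------------------------------
## HaploProfiles
## ---------------------------------------------------------------------------

#' A set of rCRS-relative sequence profiles
#'
#' Each profile is one sampled individual: an identifier, population
#' metadata, the sequencing coverage (`"complete"` genome or `"hvs1"`
#' fragment) and the set of canonical variant names relative to rCRS.
#'
#' @slot info A `data.frame` with columns `sample_id`, `population`,
#'   `region` and `coverage`.
#' @slot variants A list, parallel to the rows of `info`, of character
#'   vectors of canonical variant names.
#'
#' @seealso [readProfileTable()], [assignHaplogroups()]
#' @exportClass HaploProfiles
setClass("HaploProfiles",
  representation(info = "data.frame", variants = "list")
)

REGION_LEVELS <- c("northeastern_asia", "central_southern_siberia",
                   "eastern_asia", "india", "europe", "other")

setValidity("HaploProfiles", function(object) {
  msg <- character()
  need <- c("sample_id", "population", "region", "coverage")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns", paste(need, collapse = ", ")))
  else {
    if (nrow(object@info) != length(object@variants))
      msg <- c(msg, "one variant set per sample required")
    if (anyDuplicated(object@info$sample_id))
      msg <- c(msg, "duplicate sample_id")
    if (!all(object@info$coverage %in% c("complete", "hvs1")))
      msg <- c(msg, "coverage must be 'complete' or 'hvs1'")
    if (!all(object@info$region %in% REGION_LEVELS))
      msg <- c(msg, paste("region must be one of",
                          paste(REGION_LEVELS, collapse = ", ")))
    for (i in seq_along(object@variants)) {
      v <- object@variants[[i]]
      if (anyDuplicated(v)) {
        msg <- c(msg, sprintf("duplicate variant in profile '%s'",
                              object@info$sample_id[i]))
        break
      }
      if (object@info$coverage[i] == "hvs1" && length(v)) {
        np <- suppressWarnings(as.integer(sub("[^0-9].*$", "", v)))
        if (any(!inHVS1(np))) {
          msg <- c(msg, sprintf(
            "hvs1 profile '%s' contains variants outside nps %d-%d",
            object@info$sample_id[i], HVS1_SPAN[1], HVS1_SPAN[2]))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HaploProfiles-class Compact display.
#' @param object A `HaploProfiles`.
#' @export
setMethod("show", "HaploProfiles", function(object) {
  cat("HaploProfiles: ", nrow(object@info), " samples (",
      sum(object@info$coverage == "complete"), " complete, ",
      sum(object@info$coverage == "hvs1"), " HVS1), ",
      length(unique(object@info$population)), " populations\n", sep = "")
})

## ---------------------------------------------------------------------------
## MutationTree
## ---------------------------------------------------------------------------

#' Rooted mutation-labelled haplotype tree
#'
#' Nodes are haplotypes (rCRS-relative variant sets); node 1 is the clade
#' root (ancestral haplotype). Each non-root node's incoming edge carries an
#' ordered list of mutation events. Events are flagged `parallel` when the
#' same variant arises on more than one edge and `back` when the event
#' restores the ancestral (rCRS) state. Identical sampled profiles collapse
#' into a single node whose `multiplicity` records how many individuals
#' share the haplotype.
#'
#' @slot parent Integer vector; `parent[i]` is the parent node of node `i`
#'   (0 for the root).
#' @slot haplotype List of character vectors: the variant set of each node.
#' @slot events List of `data.frame`s (columns `name`, `gain`, `parallel`,
#'   `back`), one per node, describing the mutations on the edge above it.
#' @slot multiplicity Integer vector: sampled individuals per node (0 for
#'   purely inferred haplotypes).
#' @slot samples List of character vectors of sample ids per node.
#' @slot score Parsimony score: total number of mutation events.
#' @slot rootHaplotype Variant set of the clade root.
#'
#' @seealso [buildMPTree()], [computeRho()], [treeNewick()]
#' @exportClass MutationTree
setClass("MutationTree",
  representation(parent = "integer", haplotype = "list", events = "list",
                 multiplicity = "integer", samples = "list",
                 score = "integer", rootHaplotype = "character")
)

setValidity("MutationTree", function(object) {
  n <- length(object@parent)
  msg <- character()
  if (n < 1L || object@parent[1] != 0L)
    msg <- c(msg, "node 1 must be the root (parent 0)")
  if (n > 1L && any(object@parent[-1] < 1L | object@parent[-1] >= 2:n))
    msg <- c(msg, "nodes must be in topological order (parent index < child index)")
  if (length(object@haplotype) != n || length(object@events) != n ||
      length(object@multiplicity) != n || length(object@samples) != n)
    msg <- c(msg, "per-node slots must have one entry per node")
  if (!length(msg)) {
    ## every node's haplotype must equal root + events along its path;
    ## checked in one incremental pass (nodes are in topological order)
    replay <- vector("list", n)
    replay[[1L]] <- object@rootHaplotype
    for (i in seq_len(n)) {
      if (i > 1L) {
        ev <- object@events[[i]]
        h <- replay[[object@parent[i]]]
        if (nrow(ev))
          h <- union(setdiff(h, ev$name[!ev$gain]), ev$name[ev$gain])
        replay[[i]] <- h
      }
      if (!setequal(replay[[i]], object@haplotype[[i]])) {
        msg <- c(msg, sprintf("node %d haplotype inconsistent with edge events", i))
        break
      }
    }
    if (sum(vapply(object@events, nrow, 0L)) != object@score)
      msg <- c(msg, "score must equal the total event count")
  }
  if (length(msg)) msg else TRUE
})

## apply edge events from the root down to node i
replayEvents <- function(tree, i) {
  path <- integer()
  cur <- i
  while (cur != 0L) {
    path <- c(cur, path)
    cur <- tree@parent[cur]
  }
  h <- tree@rootHaplotype
  for (nd in path) {
    ev <- tree@events[[nd]]
    if (nrow(ev)) {
      h <- setdiff(h, ev$name[!ev$gain])
      h <- union(h, ev$name[ev$gain])
    }
  }
  h
}

#' @describeIn MutationTree-class Compact display.
#' @param object A `MutationTree`.
#' @export
setMethod("show", "MutationTree", function(object) {
  ev <- do.call(rbind, object@events)
  cat("MutationTree: ", length(object@parent), " nodes, ",
      sum(object@multiplicity), " sampled individuals\n",
      "  parsimony score ", object@score,
      " (", sum(ev$parallel), " parallel, ", sum(ev$back),
      " back events)\n", sep = "")
})

## ---------------------------------------------------------------------------
## MtClock
## ---------------------------------------------------------------------------

#' Linear molecular clock specification
#'
#' The two calibrations used for rho dating: the complete-genome clock
#' counts every post-filter substitution at one mutation per 3,624 years;
#' the synonymous clock counts only substitutions classified synonymous, at
#' one mutation per 7,884 years.
#'
#' @slot id `"complete_genome"` or `"synonymous"`.
#' @slot yearsPerMutation Years per counted mutation.
#'
#' @seealso [completeGenomeClock()], [synonymousClock()], [rhoToAge()]
#' @exportClass MtClock
setClass("MtClock",
  representation(id = "character", yearsPerMutation = "numeric")
)

setValidity("MtClock", function(object) {
  msg <- character()
  if (!object@id %in% c("complete_genome", "synonymous"))
    msg <- c(msg, "clock id must be 'complete_genome' or 'synonymous'")
  if (length(object@yearsPerMutation) != 1L || object@yearsPerMutation <= 0)
    msg <- c(msg, "yearsPerMutation must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn MtClock-class Compact display.
#' @param object An `MtClock`.
#' @export
setMethod("show", "MtClock", function(object) {
  cat("MtClock '", object@id, "': one mutation every ",
      format(object@yearsPerMutation), " years\n", sep = "")
})
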