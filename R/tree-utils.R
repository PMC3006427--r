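## Accessors and exports for MutationTree objects.

#' Query a MutationTree
#'
#' `parsimonyScore()` returns the total number of mutation events;
#' `nodeHaplotypes()` the per-node variant sets; `nodeMultiplicity()` the
#' number of sampled individuals per node; `nodeSamples()` the sample ids
#' per node; `treeParent()` the parent index of each node (0 for the
#' root); `subtreeNodes()` the node indices of the clade rooted at `node`;
#' `treeMRCA()` the most recent common ancestor of a set of nodes.
#'
#' @param tree A [MutationTree-class] object.
#' @param node,nodes Node indices.
#' @return See each description.
#' @export
parsimonyScore <- function(tree) tree@score

#' @rdname parsimonyScore
#' @export
nodeHaplotypes <- function(tree) tree@haplotype

#' @rdname parsimonyScore
#' @export
nodeMultiplicity <- function(tree) tree@multiplicity

#' @rdname parsimonyScore
#' @export
nodeSamples <- function(tree) tree@samples

#' @rdname parsimonyScore
#' @export
treeParent <- function(tree) tree@parent

#' @rdname parsimonyScore
#' @export
subtreeNodes <- function(tree, node) {
  n <- length(tree@parent)
  keep <- logical(n)
  keep[node] <- TRUE
  if (node < n) for (i in (node + 1L):n)
    if (keep[tree@parent[i]]) keep[i] <- TRUE
  which(keep)
}

#' @rdname parsimonyScore
#' @export
treeMRCA <- function(tree, nodes) {
  paths <- lapply(nodes, function(nd) {
    p <- integer()
    cur <- nd
    while (cur != 0L) { p <- c(cur, p); cur <- tree@parent[cur] }
    p
  })
  common <- Reduce(intersect, paths)
  common[length(common)]
}

## display string for one edge's events: "<" parallel, "!" back
eventString <- function(ev) {
  if (!nrow(ev)) return("")
  paste0(ifelse(ev$parallel, "<", ""), ifelse(ev$back, "!", ""), ev$name,
         collapse = ",")
}

nodeLabelString <- function(tree, i) {
  if (length(tree@samples[[i]])) paste(tree@samples[[i]], collapse = "/")
  else paste0("node", i)
}

#' Flat edge table of a MutationTree
#'
#' One row per edge with the mutation events it carries. In the `events`
#' column a `<` prefix marks a parallel mutation and `!` marks a back
#' mutation (reversion to the rCRS state).
#'
#' @param tree A [MutationTree-class] object.
#' @return A `data.frame` with columns `parent`, `child`, `n_events`,
#'   `events`, `multiplicity`, `samples`.
#' @export
treeEdgeTable <- function(tree) {
  n <- length(tree@parent)
  if (n == 1L)
    return(data.frame(parent = integer(), child = integer(),
                      n_events = integer(), events = character(),
                      multiplicity = integer(), samples = character(),
                      stringsAsFactors = FALSE))
  data.frame(parent = tree@parent[-1L], child = 2:n,
             n_events = vapply(tree@events[-1L], nrow, 0L),
             events = vapply(tree@events[-1L], eventString, ""),
             multiplicity = tree@multiplicity[-1L],
             samples = vapply(tree@samples[-1L], paste, "", collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Newick export of a MutationTree
#'
#' Writes the tree in Newick format with branch lengths equal to the
#' number of mutation events on each edge and a comment block per edge
#' listing the event names (`<` marks parallel and `!` back mutations).
#' Sampled nodes are labelled with their sample ids; inferred nodes as
#' `nodeK`.
#'
#' @param tree A [MutationTree-class] object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
treeNewick <- function(tree, file = NULL) {
  n <- length(tree@parent)
  kids <- vector("list", n)
  if (n > 1L) for (i in 2:n)
    kids[[tree@parent[i]]] <- c(kids[[tree@parent[i]]], i)
  rec <- function(i) {
    lab <- nodeLabelString(tree, i)
    ev <- tree@events[[i]]
    suffix <- if (i == 1L) "" else
      sprintf("[&mutations={%s}]:%d", eventString(ev), nrow(ev))
    if (length(kids[[i]])) {
      paste0("(", paste(vapply(kids[[i]], rec, ""), collapse = ","), ")",
             lab, suffix)
    } else {
      paste0(lab, suffix)
    }
  }
  out <- paste0(rec(1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
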