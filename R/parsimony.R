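## Maximum-parsimony reconstruction of mutation-labelled haplotype trees.
##
## Haplotypes are binary character vectors (presence/absence of each
## rCRS-relative variant). The clade root haplotype is supplied and enters
## the search as a taxon, so trees are rooted at the ancestral sequence
## type. Compatible (homoplasy-free) data are resolved directly as the
## unique perfect phylogeny; otherwise the topology space is searched
## exhaustively up to a taxon bound and by stepwise addition plus
## nearest-neighbour-interchange hill climbing above it. Fixed-topology
## scores and ancestral states come from Fitch's algorithm, which is exact
## for binary characters.

## ---------------------------------------------------------------------------
## Fitch machinery on unrooted topologies
##
## Topologies are edge matrices over node ids: leaves 1..L (leaf 1 is the
## root taxon), internal nodes L+1, ... . State sets are coded bitwise per
## character: 1 = absent, 2 = present, 3 = either.
## ---------------------------------------------------------------------------

fitchEval <- function(edges, leafCode, L, assign = FALSE) {
  nNode <- max(edges)
  adj <- vector("list", nNode)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  if (L == 2L) {
    score <- sum(bitwAnd(leafCode[, 1], leafCode[, 2]) == 0L)
    if (!assign) return(list(score = score))
    return(list(score = score, final = leafCode, adjRoot = 2L,
                parentVec = c(0L, 1L)))
  }
  start <- adj[[1L]][1L]
  code <- vector("list", nNode)
  score <- 0L
  ## iterative post-order from `start`, excluding the root leaf 1
  stack <- list(list(node = start, parent = 1L, stage = 1L))
  order <- integer()
  parentOf <- integer(nNode)
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node
    parentOf[node] <- fr$parent
    order <- c(order, node)
    for (ch in adj[[node]])
      if (ch != fr$parent)
        stack[[length(stack) + 1L]] <- list(node = ch, parent = node)
  }
  for (node in rev(order)) {
    if (node <= L) {
      code[[node]] <- leafCode[, node]
    } else {
      kids <- adj[[node]][adj[[node]] != parentOf[node]]
      acc <- code[[kids[1L]]]
      for (k in kids[-1L]) {
        inter <- bitwAnd(acc, code[[k]])
        un <- bitwOr(acc, code[[k]])
        miss <- inter == 0L
        score <- score + sum(miss)
        acc <- ifelse(miss, un, inter)
      }
      code[[node]] <- acc
    }
  }
  topInter <- bitwAnd(code[[start]], leafCode[, 1L])
  score <- score + sum(topInter == 0L)
  if (!assign) return(list(score = score))
  ## top-down refinement: root state is the root taxon's (definite) state
  final <- matrix(0L, nrow = nrow(leafCode), ncol = nNode)
  final[, 1L] <- leafCode[, 1L]
  for (node in order) {
    s <- final[, parentOf[node]]
    cc <- code[[node]]
    hit <- bitwAnd(cc, s) > 0L
    final[, node] <- ifelse(hit, s, cc)
  }
  list(score = score, final = final, adjRoot = start, parentVec = parentOf)
}

## enumerate all unrooted binary topologies over L >= 3 leaves in a fixed
## deterministic order, calling fun(edges) on each
enumTopologies <- function(L, fun) {
  base <- rbind(c(1L, L + 1L), c(2L, L + 1L), c(3L, L + 1L))
  recur <- function(edges, nextLeaf, nextInternal) {
    if (nextLeaf > L) {
      fun(edges)
      return(invisible())
    }
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      newEdges <- rbind(edges[-e, , drop = FALSE],
                        c(u, nextInternal), c(nextInternal, v),
                        c(nextLeaf, nextInternal))
      recur(newEdges, nextLeaf + 1L, nextInternal + 1L)
    }
  }
  recur(base, 4L, L + 2L)
}

## greedy stepwise addition followed by NNI hill climbing
stepwiseNNI <- function(leafCode, L) {
  edges <- rbind(c(1L, L + 1L), c(2L, L + 1L), c(3L, L + 1L))
  nextInternal <- L + 2L
  for (leaf in seq(4L, length.out = max(0L, L - 3L))) {
    best <- NULL; bestScore <- Inf
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      cand <- rbind(edges[-e, , drop = FALSE],
                    c(u, nextInternal), c(nextInternal, v),
                    c(leaf, nextInternal))
      sc <- fitchEval(cand, leafCode[, seq_len(leaf), drop = FALSE],
                      leaf)$score
      if (sc < bestScore) { bestScore <- sc; best <- cand }
    }
    edges <- best
    nextInternal <- nextInternal + 1L
  }
  ## NNI until no improvement
  score <- fitchEval(edges, leafCode, L)$score
  edgeRow <- function(m, a, b)
    which((m[, 1] == a & m[, 2] == b) | (m[, 1] == b & m[, 2] == a))
  repeat {
    improved <- FALSE
    internal <- which(edges[, 1] > L & edges[, 2] > L)
    for (e in internal) {
      u <- edges[e, 1]; v <- edges[e, 2]
      un <- setdiff(c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1]), v)
      vn <- setdiff(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]), u)
      for (swapWith in vn) {
        ## exchange the subtree un[1] (hanging off u) with swapWith (off v)
        cand <- edges
        cand[edgeRow(edges, u, un[1]), ] <- c(u, swapWith)
        cand[edgeRow(edges, v, swapWith), ] <- c(v, un[1])
        sc <- fitchEval(cand, leafCode, L)$score
        if (sc < score) { edges <- cand; score <- sc; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(edges = edges, score = score)
}

## ---------------------------------------------------------------------------
## Perfect-phylogeny kernel and tree assembly
## ---------------------------------------------------------------------------

## derived-taxon clusters per character, polarized by the root state
characterClusters <- function(leafCode, rootState) {
  lapply(seq_len(nrow(leafCode)), function(c) {
    which(leafCode[c, ] != (if (rootState[c]) 2L else 1L))
  })
}

## laminar family test: every pair of clusters disjoint or nested
clustersCompatible <- function(clusters) {
  keys <- vapply(clusters, paste, "", collapse = ",")
  uq <- clusters[!duplicated(keys)]
  if (length(uq) < 2L) return(TRUE)
  for (i in seq_len(length(uq) - 1L)) for (j in (i + 1L):length(uq)) {
    ab <- intersect(uq[[i]], uq[[j]])
    if (length(ab) && length(ab) < min(length(uq[[i]]), length(uq[[j]])))
      return(FALSE)
  }
  TRUE
}

#' Reconstruct the most-parsimonious mutation-labelled tree
#'
#' Builds a rooted haplotype tree for a set of profiles within one clade,
#' rooted at a supplied ancestral haplotype (normally the haplogroup
#' founder motif from the nomenclature). Identical profiles collapse into
#' one node with a multiplicity count. When all variant sites are mutually
#' compatible the unique perfect phylogeny is returned directly; otherwise
#' all topologies are scored exhaustively up to `exhaustiveBound` distinct
#' haplotypes (root included) and larger instances are resolved by stepwise
#' addition with nearest-neighbour-interchange hill climbing. Ties between
#' equally parsimonious trees are broken by the deterministic enumeration
#' order (taxa sorted by haplotype key). Events that recur on separate
#' edges are flagged `parallel`; events restoring the rCRS state are
#' flagged `back`.
#'
#' Profiles are expected to be pre-filtered with [applyExclusionFilters()];
#' the function does not filter.
#'
#' @param x A [HaploProfiles-class] object, or a named list of character
#'   vectors of canonical variant names.
#' @param rootHaplotype Character vector: the clade root's variant set
#'   relative to rCRS (default empty, i.e. the reference itself).
#' @param exhaustiveBound Maximum number of distinct haplotypes (root
#'   included) for exhaustive topology search; default 8.
#' @return A [MutationTree-class] object.
#' @examples
#' tr <- buildMPTree(list(A = "100", B = c("100", "200"), C = "300"))
#' parsimonyScore(tr)
#' @export
buildMPTree <- function(x, rootHaplotype = character(),
                        exhaustiveBound = 8L) {
  if (is(x, "HaploProfiles")) {
    varsets <- setNames(x@variants, x@info$sample_id)
  } else {
    varsets <- lapply(x, as.character)
    if (is.null(names(varsets)))
      names(varsets) <- paste0("S", seq_along(varsets))
  }
  if (!length(varsets)) stop("at least one profile is required")
  ## haploid model check: one state per substituted position per profile
  for (id in names(varsets)) {
    v <- varsets[[id]]
    sub <- v[grepl("^[0-9]+[ACGT]?$", v)]
    if (anyDuplicated(variantNp(sub)))
      stop(sprintf(
        "profile '%s' carries two states at one position: conflicts with the haploid root model",
        id))
  }
  rootHaplotype <- unique(as.character(rootHaplotype))
  key <- vapply(varsets, function(v) paste(sort(v), collapse = ","), "")
  rootKey <- paste(sort(rootHaplotype), collapse = ",")
  haploKeys <- sort(unique(key[key != rootKey]))
  taxaSets <- c(list(rootHaplotype),
                lapply(haploKeys, function(k)
                  varsets[[match(k, key)]]))
  L <- length(taxaSets)
  taxSamples <- c(list(names(varsets)[key == rootKey]),
                  lapply(haploKeys, function(k) names(varsets)[key == k]))
  allVars <- sort(unique(unlist(taxaSets)))
  cnt <- table(unlist(lapply(taxaSets, unique)))
  base <- names(cnt)[cnt == L]
  chars <- setdiff(allVars, base)
  rootState <- chars %in% rootHaplotype
  if (!length(chars) || L == 1L) {
    tree <- new("MutationTree", parent = 0L,
                haplotype = list(rootHaplotype),
                events = list(emptyEventTable()),
                multiplicity = length(varsets),
                samples = list(names(varsets)),
                score = 0L, rootHaplotype = rootHaplotype)
    return(tree)
  }
  leafCode <- matrix(1L, nrow = length(chars), ncol = L)
  for (t in seq_len(L))
    leafCode[chars %in% taxaSets[[t]], t] <- 2L
  clusters <- characterClusters(leafCode, rootState)
  if (clustersCompatible(clusters)) {
    return(perfectPhylogeny(chars, rootState, clusters, taxaSets,
                            taxSamples, rootHaplotype, L))
  }
  if (L <= exhaustiveBound && L >= 3L) {
    ## minimise the event count; among ties prefer the fewest back
    ## mutations (losses), then the first topology in enumeration order
    bestScore <- Inf
    bestBack <- Inf
    bestEdges <- NULL
    enumTopologies(L, function(edges) {
      sc <- fitchEval(edges, leafCode, L)$score
      if (sc > bestScore) return(invisible())
      nb <- sankoffEval(edges, leafCode, L)$losses
      if (sc < bestScore || nb < bestBack) {
        bestScore <<- sc; bestBack <<- nb; bestEdges <<- edges
      }
    })
    fit <- sankoffEval(bestEdges, leafCode, L)
    edges <- bestEdges
  } else if (L == 2L) {
    edges <- rbind(c(1L, 2L))
    fit <- sankoffEval(edges, leafCode, L)
  } else {
    sw <- stepwiseNNI(leafCode, L)
    edges <- sw$edges
    fit <- sankoffEval(edges, leafCode, L)
  }
  assembleTree(chars, fit, edges, L, base, taxSamples, rootHaplotype)
}

## Optimal ancestral states by dynamic programming with lexicographic cost
## (total events, loss events): among maximum-parsimony labelings of a fixed
## topology, the one with fewest reversions is chosen, matching the
## convention of drawing recurrent gains as parallel mutations rather than
## gain-plus-back-mutation chains. Costs are packed as events*1024 + losses.
sankoffEval <- function(edges, leafCode, L) {
  GAIN <- 2^20; LOSS <- 2^20 + 1; INF <- 1e12
  nNode <- max(edges)
  adj <- vector("list", nNode)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nc <- nrow(leafCode)
  if (L == 2L) {
    total <- sum(ifelse(leafCode[, 1] == leafCode[, 2], 0,
                        ifelse(leafCode[, 2] == 2L, GAIN, LOSS)))
    return(list(score = as.integer(total %/% 2^20), losses = as.integer(total %% 2^20),
                final = leafCode, parentVec = c(0L, 1L)))
  }
  start <- adj[[1L]][1L]
  stack <- list(list(node = start, parent = 1L))
  order <- integer()
  parentOf <- integer(nNode)
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    parentOf[fr$node] <- fr$parent
    order <- c(order, fr$node)
    for (ch in adj[[fr$node]])
      if (ch != fr$parent)
        stack[[length(stack) + 1L]] <- list(node = ch, parent = fr$node)
  }
  costA <- matrix(0, nrow = nc, ncol = nNode)   # node state = absent
  costP <- matrix(0, nrow = nc, ncol = nNode)   # node state = present
  for (node in rev(order)) {
    if (node <= L) {
      costA[, node] <- ifelse(leafCode[, node] == 1L, 0, INF)
      costP[, node] <- ifelse(leafCode[, node] == 2L, 0, INF)
    } else {
      for (k in adj[[node]][adj[[node]] != parentOf[node]]) {
        costA[, node] <- costA[, node] + pmin(costA[, k], costP[, k] + GAIN)
        costP[, node] <- costP[, node] + pmin(costA[, k] + LOSS, costP[, k])
      }
    }
  }
  rootState <- leafCode[, 1L]
  totals <- ifelse(rootState == 1L,
                   pmin(costA[, start], costP[, start] + GAIN),
                   pmin(costA[, start] + LOSS, costP[, start]))
  final <- matrix(0L, nrow = nc, ncol = nNode)
  final[, 1L] <- rootState
  for (node in order) {
    s <- final[, parentOf[node]]
    fromA <- ifelse(s == 1L, costA[, node], costA[, node] + LOSS)
    fromP <- ifelse(s == 2L, costP[, node], costP[, node] + GAIN)
    ## prefer no change on ties
    final[, node] <- ifelse(fromA < fromP, 1L,
                     ifelse(fromP < fromA, 2L, s))
  }
  list(score = as.integer(sum(totals) %/% 2^20),
       losses = as.integer(sum(totals) %% 2^20),
       final = final, parentVec = parentOf)
}

emptyEventTable <- function() {
  data.frame(name = character(), gain = logical(), parallel = logical(),
             back = logical(), stringsAsFactors = FALSE)
}

orderEvents <- function(ev) {
  ev[order(variantNp(ev$name), ev$name), , drop = FALSE]
}

## flag parallel (same variant, same direction, >1 edge) and back
## (restores the rCRS state, i.e. a loss) events across the whole tree
flagEvents <- function(events) {
  all <- do.call(rbind, lapply(seq_along(events), function(i)
    if (nrow(events[[i]])) cbind(events[[i]], node = i)))
  if (is.null(all) || !nrow(all)) return(events)
  dirKey <- paste(all$name, all$gain)
  recur <- names(which(table(dirKey) > 1L))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!nrow(ev)) next
    ev$parallel <- paste(ev$name, ev$gain) %in% recur
    ev$back <- !ev$gain
    events[[i]] <- orderEvents(ev)
    rownames(events[[i]]) <- NULL
  }
  events
}

## direct construction for mutually compatible characters
perfectPhylogeny <- function(chars, rootState, clusters, taxaSets,
                             taxSamples, rootHaplotype, L) {
  keyOf <- vapply(clusters, function(s) paste(s, collapse = ","), "")
  uqKeys <- unique(keyOf)
  uqSets <- clusters[match(uqKeys, keyOf)]
  ## order clusters by decreasing size, then lexicographic key
  ord <- order(-lengths(uqSets), uqKeys)
  uqSets <- uqSets[ord]
  uqKeys <- uqKeys[ord]
  nodeOf <- integer(length(uqSets))          # MT node per cluster
  parent <- 0L
  haplo <- list(rootHaplotype)
  events <- list(emptyEventTable())
  nNode <- 1L
  for (i in seq_along(uqSets)) {
    ## parent cluster: smallest strictly containing, already placed
    par <- 1L
    for (j in seq_len(i - 1L)) {
      if (all(uqSets[[i]] %in% uqSets[[j]]) &&
          length(uqSets[[j]]) > length(uqSets[[i]]))
        par <- nodeOf[j]                     # later j = smaller superset
    }
    nNode <- nNode + 1L
    nodeOf[i] <- nNode
    parent[nNode] <- par
    members <- chars[keyOf == uqKeys[i]]
    gain <- !rootState[match(members, chars)]
    events[[nNode]] <- data.frame(name = members, gain = gain,
                                  parallel = FALSE, back = !gain,
                                  stringsAsFactors = FALSE)
    h <- haplo[[par]]
    haplo[[nNode]] <- union(setdiff(h, members[!gain]), members[gain])
  }
  ## attach taxa to the node of the smallest cluster containing them
  mult <- integer(nNode)
  samples <- rep(list(character()), nNode)
  for (t in seq_len(L)) {
    node <- 1L
    bestSize <- Inf
    for (i in seq_along(uqSets)) {
      if (t %in% uqSets[[i]] && length(uqSets[[i]]) < bestSize) {
        bestSize <- length(uqSets[[i]])
        node <- nodeOf[i]
      }
    }
    mult[node] <- mult[node] + length(taxSamples[[t]])
    samples[[node]] <- c(samples[[node]], taxSamples[[t]])
  }
  events <- flagEvents(events)
  new("MutationTree", parent = parent, haplotype = haplo, events = events,
      multiplicity = mult, samples = samples,
      score = sum(vapply(events, nrow, 0L)),
      rootHaplotype = rootHaplotype)
}

## build a MutationTree from a scored topology and its Fitch assignment
assembleTree <- function(chars, fit, edges, L, base, taxSamples,
                         rootHaplotype) {
  final <- fit$final
  parentVec <- fit$parentVec
  nTopo <- max(edges)
  kids <- vector("list", nTopo)
  for (n in seq_len(nTopo))
    if (n != 1L && parentVec[n] > 0L)
      kids[[parentVec[n]]] <- c(kids[[parentVec[n]]], n)
  if (L == 2L) { kids[[1L]] <- 2L; parentVec <- c(0L, 1L) }
  ## BFS from the root taxon (topology leaf 1)
  bfs <- 1L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unlist(kids[frontier])
    bfs <- c(bfs, nxt)
    frontier <- nxt
  }
  mtIndex <- integer(nTopo)
  mtIndex[1L] <- 1L
  parent <- 0L
  haplo <- list(rootHaplotype)
  events <- list(emptyEventTable())
  mult <- 0L
  samples <- list(character())
  nNode <- 1L
  stateOf <- function(n) {
    if (L == 2L && n <= 2L) return(final[, n])
    final[, n]
  }
  for (n in bfs[-1L]) {
    p <- parentVec[n]
    diffs <- which(stateOf(n) != stateOf(p))
    if (!length(diffs)) {
      mtIndex[n] <- mtIndex[p]
    } else {
      nNode <- nNode + 1L
      mtIndex[n] <- nNode
      parent[nNode] <- mtIndex[p]
      gain <- stateOf(n)[diffs] == 2L
      events[[nNode]] <- data.frame(name = chars[diffs], gain = gain,
                                    parallel = FALSE, back = !gain,
                                    stringsAsFactors = FALSE)
      haplo[[nNode]] <- union(base, chars[stateOf(n) == 2L])
      mult[nNode] <- 0L
      samples[[nNode]] <- character()
    }
  }
  haplo[[1L]] <- rootHaplotype
  for (t in seq_len(L)) {
    node <- mtIndex[t]
    mult[node] <- mult[node] + length(taxSamples[[t]])
    samples[[node]] <- c(samples[[node]], taxSamples[[t]])
  }
  events <- flagEvents(events)
  new("MutationTree", parent = parent, haplotype = haplo, events = events,
      multiplicity = mult, samples = samples,
      score = sum(vapply(events, nrow, 0L)),
      rootHaplotype = rootHaplotype)
}
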