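## Synthetic mtDNA evolution with known genealogy and TMRCA.
##
## Sequences evolve along a star, Kingman-coalescent or user-supplied time
## tree. Mutation events are Poisson on branch lengths at the clock's rate
## (one event per `yearsPerMutation` years), sites are drawn
## hotspot-weighted, transitions outweigh transversions by `tsTvRatio`,
## and under the synonymous clock candidate sites are restricted to
## positions with a possible synonymous change. Infinite-sites mode (the
## default) never hits a site twice, separating estimator behaviour from
## homoplasy handling; finite-sites mode generates deliberate parallel and
## back mutations for parsimony tests.

#' Build a simulation configuration
#'
#' @param nSamples Number of sampled sequences (>= 1).
#' @param genealogy `"star"`, `"kingman_coalescent"` or `"fixed_tree"`.
#' @param tmrcaYears For a star genealogy, the age of the radiation in
#'   years (every tip sits this far from the root). For the coalescent,
#'   the time-scale parameter in years (the expected TMRCA approaches
#'   `2 * tmrcaYears` for large samples).
#' @param clock An [MtClock-class] object setting the event rate and, for
#'   the synonymous clock, the candidate-site restriction.
#' @param tsTvRatio Transition:transversion ratio (default 20, the order
#'   observed in human mtDNA).
#' @param hotspotMultipliers Named numeric vector of per-position rate
#'   multipliers (names are nps), default none.
#' @param populations `data.frame` with columns `name`, `region`, `weight`;
#'   samples are assigned to populations with these probabilities.
#' @param seed Integer seed; fully determines the output.
#' @param infiniteSites Never mutate the same position twice (default
#'   `TRUE`).
#' @param rootHaplotype Canonical variant names carried by the genealogy
#'   root (e.g. a haplogroup motif); substitutions only.
#' @param fixedTree An [ape::phylo] tree with branch lengths in years
#'   (required when `genealogy = "fixed_tree"`).
#' @return A validated configuration list of class `mtSimConfig`.
#' @export
simulationConfig <- function(nSamples,
                             genealogy = c("star", "kingman_coalescent",
                                           "fixed_tree"),
                             tmrcaYears = 10000,
                             clock = completeGenomeClock(),
                             tsTvRatio = 20,
                             hotspotMultipliers = numeric(),
                             populations = data.frame(
                               name = "SimPop", region = "other",
                               weight = 1, stringsAsFactors = FALSE),
                             seed = 1L,
                             infiniteSites = TRUE,
                             rootHaplotype = character(),
                             fixedTree = NULL) {
  genealogy <- match.arg(genealogy)
  if (nSamples < 1L) stop("nSamples must be >= 1")
  if (tmrcaYears <= 0) stop("tmrcaYears must be positive")
  if (tsTvRatio <= 0) stop("tsTvRatio must be positive")
  if (abs(sum(populations$weight) - 1) > 1e-8)
    stop("population weights must sum to 1")
  if (!all(populations$region %in% REGION_LEVELS))
    stop("unknown region in populations")
  if (genealogy == "fixed_tree" && !inherits(fixedTree, "phylo"))
    stop("fixed_tree genealogy requires an ape::phylo in fixedTree")
  structure(list(nSamples = as.integer(nSamples), genealogy = genealogy,
                 tmrcaYears = tmrcaYears, clock = clock,
                 tsTvRatio = tsTvRatio,
                 hotspotMultipliers = hotspotMultipliers,
                 populations = populations, seed = as.integer(seed),
                 infiniteSites = infiniteSites,
                 rootHaplotype = unique(as.character(rootHaplotype)),
                 fixedTree = fixedTree),
            class = "mtSimConfig")
}

#' Simulate a time-calibrated genealogy
#'
#' Star genealogies place every tip at `tmrcaYears` from the root;
#' Kingman coalescent genealogies are drawn with [ape::rcoal] and scaled
#' so one coalescent time unit equals `tmrcaYears` years. Deterministic
#' given the configuration seed.
#'
#' @param config An `mtSimConfig` from [simulationConfig()].
#' @return An [ape::phylo] tree with branch lengths in years and
#'   attribute `tmrcaYears` (the realised root-to-tip time).
#' @export
simulateGenealogy <- function(config) {
  stopifnot(inherits(config, "mtSimConfig"))
  n <- config$nSamples
  tips <- sprintf("S%03d", seq_len(n))
  tree <- withLocalSeed(config$seed, {
    if (config$genealogy == "star") {
      tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = rep(config$tmrcaYears, n),
                 tip.label = tips, Nnode = 1L)
      class(tr) <- "phylo"
      attr(tr, "order") <- "cladewise"
      tr
    } else if (config$genealogy == "kingman_coalescent") {
      if (n < 2L) stop("coalescent genealogies need nSamples >= 2")
      tr <- ape::rcoal(n, tip.label = tips)
      tr$edge.length <- tr$edge.length * config$tmrcaYears
      tr
    } else {
      tr <- config$fixedTree
      if (length(tr$tip.label) != n)
        stop("fixedTree tip count must equal nSamples")
      tr
    }
  })
  depths <- ape::node.depth.edgelength(tree)
  attr(tree, "tmrcaYears") <- max(depths[seq_len(n)])
  tree
}

## candidate mutation table for a clock: np, alt, weight
candidateSites <- function(config, ref) {
  seqChars <- refCharVec(ref)
  if (config$clock@id == "synonymous") {
    cand <- synonymousChanges(ref)
  } else {
    np <- setdiff(seq_len(MT_LENGTH), PLACEHOLDER_NP)
    rb <- seqChars[np]
    cand <- rbind(
      data.frame(np = np, alt = unname(TRANSITION_PARTNER[rb]),
                 mclass = "transition", stringsAsFactors = FALSE),
      do.call(rbind, lapply(DNA_BASES, function(b) {
        sel <- rb != b & unname(TRANSITION_PARTNER[rb]) != b
        data.frame(np = np[sel], alt = b, mclass = "transversion",
                   stringsAsFactors = FALSE)
      })))
  }
  w <- ifelse(cand$mclass == "transition", config$tsTvRatio, 0.5)
  hot <- config$hotspotMultipliers
  if (length(hot)) {
    idx <- match(as.character(cand$np), names(hot))
    w <- w * ifelse(is.na(idx), 1, hot[idx])
  }
  cand$weight <- w
  cand$ref <- seqChars[cand$np]
  cand
}

#' Evolve sequences along a time tree
#'
#' Drops Poisson(`branch length / yearsPerMutation`) mutation events on
#' each branch, materialises the tip sequences, and returns them together
#' with the full ground truth: per-sample variant sets, the true
#' mutation-labelled tree, and the realised TMRCA. Uses the RNG stream
#' seeded with `config$seed + 1` (the genealogy uses `config$seed`), so a
#' configuration reproduces a dataset exactly.
#'
#' @param tree A time tree from [simulateGenealogy()].
#' @param config An `mtSimConfig`.
#' @param ref An [MtReference-class] object.
#' @param sequences Materialise tip sequences (default `TRUE`; turn off to
#'   simulate variant sets only).
#' @return A list with elements `sequences` (named character vector, or
#'   `NULL`), `profiles` (a [HaploProfiles-class]), `variantSets` (named
#'   list), `trueTree` (a [MutationTree-class]), `tmrcaYears`, and
#'   `eventsPerTip` (root-to-tip event counts).
#' @export
evolveSequences <- function(tree, config, ref, sequences = TRUE) {
  stopifnot(inherits(config, "mtSimConfig"))
  rootVars <- parseVariants(config$rootHaplotype, ref)
  if (nrow(rootVars) &&
      !all(rootVars$mclass %in% c("transition", "transversion")))
    stop("rootHaplotype must contain substitutions only")
  cand <- candidateSites(config, ref)
  refByNp <- character(MT_LENGTH)
  refByNp[cand$np] <- cand$ref
  n <- length(tree$tip.label)
  nNode <- max(tree$edge)
  withLocalSeed(config$seed + 1L, {
    if (config$infiniteSites) {
      blocked <- cand$np %in% rootVars$np
      cand <- cand[!blocked, , drop = FALSE]
    }
    available <- rep(TRUE, nrow(cand))
    ## weighted site draws by inversion on the cumulative weights, with
    ## rejection of already-used sites (exact under infinite sites because
    ## relative weights of the remaining sites are unchanged)
    cumw <- cumsum(cand$weight)
    drawSite <- function() {
      for (t in 1:50) {
        i <- findInterval(runif(1, 0, cumw[length(cumw)]), cumw) + 1L
        if (!config$infiniteSites || available[i]) return(i)
      }
      pool <- which(available)
      if (!length(pool)) return(NA_integer_)
      pool[sample.int(length(pool), 1L, prob = cand$weight[pool])]
    }
    ## state per phylo node: named vector np -> current base (diffs only)
    state <- vector("list", nNode)
    rootNode <- n + 1L
    st0 <- setNames(rootVars$alt, rootVars$np)
    state[[rootNode]] <- st0
    edgeEvents <- vector("list", nrow(tree$edge))
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      st <- state[[par]]
      k <- rpois(1L, tree$edge.length[e] / config$clock@yearsPerMutation)
      ev <- list()
      for (j in seq_len(k)) {
        pick <- drawSite()
        if (is.na(pick)) break
        np <- cand$np[pick]
        if (config$infiniteSites) {
          available[cand$np == np] <- FALSE
          from <- cand$ref[pick]
          to <- cand$alt[pick]
        } else {
          from <- if (as.character(np) %in% names(st))
            st[[as.character(np)]] else cand$ref[pick]
          to <- cand$alt[pick]
          if (to == from) {  # re-draw towards any different base
            to <- sample(setdiff(DNA_BASES, from), 1L)
          }
        }
        ev[[length(ev) + 1L]] <- c(np = np, from = from, to = to)
        if (to == refByNp[np]) st <- st[names(st) != np] else
          st[as.character(np)] <- to
      }
      edgeEvents[[e]] <- ev
      state[[child]] <- st
    }
    ## canonical variant sets per node
    nodeVars <- lapply(state, function(st) {
      if (!length(st)) return(character())
      np <- as.integer(names(st))
      sort(substitutionName(np, refByNp[np], unname(st)))
    })
    variantSets <- setNames(nodeVars[seq_len(n)], tree$tip.label)
    truth <- truthTree(tree, nodeVars, nodeVars[[rootNode]])
    pops <- config$populations
    popIdx <- sample.int(nrow(pops), n, replace = TRUE, prob = pops$weight)
    profiles <- new("HaploProfiles",
                    info = data.frame(sample_id = tree$tip.label,
                                      population = pops$name[popIdx],
                                      region = pops$region[popIdx],
                                      coverage = "complete",
                                      stringsAsFactors = FALSE),
                    variants = unname(variantSets))
    seqs <- NULL
    if (sequences) {
      refChars <- refCharVec(ref)
      seqs <- vapply(seq_len(n), function(i) {
        s <- refChars
        st <- state[[i]]
        if (length(st)) s[as.integer(names(st))] <- unname(st)
        paste(s, collapse = "")
      }, "")
      names(seqs) <- tree$tip.label
    }
    depths <- ape::node.depth.edgelength(tree)
    eventsPerTip <- setNames(vapply(seq_len(n), function(i)
      length(setdiff(union(variantSets[[i]], nodeVars[[rootNode]]),
                     intersect(variantSets[[i]], nodeVars[[rootNode]]))),
      0L), tree$tip.label)
    list(sequences = seqs, profiles = profiles, variantSets = variantSets,
         trueTree = truth, tmrcaYears = max(depths[seq_len(n)]),
         eventsPerTip = eventsPerTip)
  })
}

## assemble the true MutationTree from the genealogy: each branch carries
## the net state changes between its endpoint haplotypes (under finite
## sites a site hit twice on one branch contributes only its net change)
truthTree <- function(tree, nodeVars, rootSet) {
  n <- length(tree$tip.label)
  nNode <- max(tree$edge)
  rootNode <- n + 1L
  ## map phylo nodes to topological order (root first)
  mtIdx <- integer(nNode)
  mtIdx[rootNode] <- 1L
  parent <- 0L
  events <- list(emptyEventTable())
  haplo <- list(rootSet)
  mult <- 0L
  samples <- list(character())
  cnt <- 1L
  for (e in seq_len(nrow(tree$edge))) {   # cladewise: parents first
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    cnt <- cnt + 1L
    mtIdx[child] <- cnt
    parent[cnt] <- mtIdx[par]
    gains <- setdiff(nodeVars[[child]], nodeVars[[par]])
    losses <- setdiff(nodeVars[[par]], nodeVars[[child]])
    if (length(gains) + length(losses)) {
      gl <- c(rep(FALSE, length(losses)), rep(TRUE, length(gains)))
      events[[cnt]] <- data.frame(name = c(losses, gains), gain = gl,
                                  parallel = FALSE, back = !gl,
                                  stringsAsFactors = FALSE)
    } else {
      events[[cnt]] <- emptyEventTable()
    }
    haplo[[cnt]] <- nodeVars[[child]]
    mult[cnt] <- if (child <= n) 1L else 0L
    samples[[cnt]] <- if (child <= n) tree$tip.label[child] else character()
  }
  events <- flagEvents(events)
  new("MutationTree", parent = parent, haplotype = haplo, events = events,
      multiplicity = mult, samples = samples,
      score = sum(vapply(events, nrow, 0L)), rootHaplotype = rootSet)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulateGenealogy()] then [evolveSequences()].
#'
#' @inheritParams evolveSequences
#' @param config An `mtSimConfig`.
#' @param ref An [MtReference-class] object.
#' @return As [evolveSequences()], plus element `genealogy` (the time
#'   tree).
#' @export
simulateDataset <- function(config, ref, sequences = TRUE) {
  tree <- simulateGenealogy(config)
  out <- evolveSequences(tree, config, ref, sequences = sequences)
  out$genealogy <- tree
  out
}
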