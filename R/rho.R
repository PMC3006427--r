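## Rho divergence statistic, Saillard standard error and clock conversion.

#' The two linear molecular clocks
#'
#' `completeGenomeClock()` counts every substitution event (transitions and
#' transversions; indels never count) at one mutation per 3,624 years.
#' `synonymousClock()` counts only substitutions classified synonymous, at
#' one mutation per 7,884 years.
#'
#' @return An [MtClock-class] object.
#' @examples
#' completeGenomeClock()
#' @export
completeGenomeClock <- function()
  new("MtClock", id = "complete_genome", yearsPerMutation = 3624)

#' @rdname completeGenomeClock
#' @export
synonymousClock <- function()
  new("MtClock", id = "synonymous", yearsPerMutation = 7884)

## does one edge event count under the clock? Back mutations count as one
## event and are classified by the site change they revert.
countedEventMask <- function(ev, clock, ref, synCache = NULL) {
  if (!nrow(ev)) return(logical(0))
  isSub <- grepl("^[0-9]+[ACGT]?$", ev$name)
  if (clock@id == "complete_genome") return(isSub)
  if (is.null(ref))
    stop("the synonymous clock needs the reference genome (ref)")
  out <- logical(nrow(ev))
  for (i in which(isSub)) {
    nm <- ev$name[i]
    if (!is.null(synCache) && !is.null(synCache[[nm]])) {
      out[i] <- synCache[[nm]]
    } else {
      v <- parseVariants(nm, ref)
      cls <- classifySubstitution(ref, v$np, v$alt)$category
      out[i] <- cls == "synonymous"
      if (!is.null(synCache)) synCache[[nm]] <- out[i]
    }
  }
  out
}

#' Rho statistic and Saillard standard error for a clade
#'
#' Rho is the average number of counted mutation events separating the
#' sampled individuals of a clade from its root haplotype, each individual
#' weighted by its multiplicity. Its standard error follows the
#' branch-structure estimator: `sigma^2 = (1/n^2) * sum_b l_b * n_b^2`,
#' where `l_b` is the number of counted events on branch `b` and `n_b` the
#' number of sampled individuals below it; for a star genealogy this
#' reduces to `sigma = sqrt(rho / n)`.
#'
#' @param tree A [MutationTree-class] object.
#' @param clock An [MtClock-class] object (default the complete-genome
#'   clock).
#' @param ref An [MtReference-class] object; required for the synonymous
#'   clock.
#' @param clade Node index of the clade root (default 1, the tree root).
#' @return A list with elements `rho`, `sigma` and `n`.
#' @examples
#' tr <- buildMPTree(list(A = "100", B = "200", C = "300", D = "400"))
#' computeRho(tr)  # star: rho = 1, sigma = 0.5
#' @export
computeRho <- function(tree, clock = completeGenomeClock(), ref = NULL,
                       clade = 1L) {
  n <- length(tree@parent)
  if (clade < 1L || clade > n) stop("clade is not a node of the tree")
  nodes <- subtreeNodes(tree, clade)
  nTot <- sum(tree@multiplicity[nodes])
  if (nTot == 0L) stop("clade contains no sampled individuals")
  synCache <- new.env(parent = emptyenv())
  counted <- setNames(rep(0L, n), seq_len(n))
  for (i in nodes) if (i != clade)
    counted[i] <- sum(countedEventMask(tree@events[[i]], clock, ref,
                                       synCache))
  ## path event counts from the clade root, then the branch-wise sigma
  depthEv <- setNames(rep(0, n), seq_len(n))
  for (i in nodes) if (i != clade)
    depthEv[i] <- depthEv[tree@parent[i]] + counted[i]
  rho <- sum(tree@multiplicity[nodes] * depthEv[nodes]) / nTot
  nBelow <- setNames(as.numeric(tree@multiplicity), seq_len(n))
  for (i in rev(nodes)) if (i != clade)
    nBelow[tree@parent[i]] <- nBelow[tree@parent[i]] + nBelow[i]
  sigma2 <- sum(vapply(setdiff(nodes, clade), function(i)
    counted[i] * nBelow[i]^2, 0)) / nTot^2
  list(rho = rho, sigma = sqrt(sigma2), n = nTot)
}

#' Convert a rho estimate to a calendar age
#'
#' Linear conversion: `age = rho * yearsPerMutation`, with the one-sigma
#' error range `(rho -/+ sigma) * yearsPerMutation`, floored at zero.
#'
#' @param rho,sigma Non-negative reals (from [computeRho()]).
#' @param clock An [MtClock-class] object.
#' @param clade Optional clade label for the output row.
#' @param n Optional number of sampled sequences for the output row.
#' @return A one-row `data.frame` with columns `clade`, `n`, `rho`,
#'   `sigma`, `clock`, `age_years`, `ci_low_years`, `ci_high_years`.
#' @examples
#' rhoToAge(1, 0, completeGenomeClock())$age_years  # 3624
#' @export
rhoToAge <- function(rho, sigma, clock, clade = NA_character_,
                     n = NA_integer_) {
  if (rho < 0 || sigma < 0) stop("rho and sigma must be non-negative")
  age <- rho * clock@yearsPerMutation
  data.frame(clade = clade, n = n, rho = rho, sigma = sigma,
             clock = clock@id,
             age_years = age,
             ci_low_years = max(0, (rho - sigma) * clock@yearsPerMutation),
             ci_high_years = (rho + sigma) * clock@yearsPerMutation,
             stringsAsFactors = FALSE)
}

#' Age estimates for every labelled clade of a tree
#'
#' Assigns every sampled haplotype of the tree to a haplogroup, then, for
#' each haplogroup with sampled members (and each of its nomenclature
#' ancestors down to the deepest label covering all members), computes rho
#' and sigma at the most recent common ancestor node of the members and
#' converts to calendar ages under each clock. Ages are reported in ky, in
#' the usual paired format: the complete-genome clock first, the
#' synonymous clock second.
#'
#' @param tree A [MutationTree-class] object.
#' @param nomenclature A [HaploNomenclature-class] object.
#' @param ref An [MtReference-class] object (needed for the synonymous
#'   clock).
#' @param clocks List of [MtClock-class] objects; default both clocks.
#' @return A `data.frame` with columns `clade`, `n`, `rho`, `sigma`,
#'   `clock`, `age_ky`, `ci_low_ky`, `ci_high_ky`, ordered by clade then
#'   clock.
#' @export
dateAllClades <- function(tree, nomenclature, ref = NULL,
                          clocks = list(completeGenomeClock(),
                                        synonymousClock())) {
  sampled <- which(tree@multiplicity > 0L)
  lab <- vapply(sampled, function(i)
    assignHaplogroup(tree@haplotype[[i]], nomenclature)$label, "")
  ## members of a clade label: sampled nodes assigned to it or any
  ## descendant label
  labs <- unique(lab)
  allLabs <- unique(unlist(lapply(labs, rootPath, tree = nomenclature)))
  rows <- list()
  for (L in allLabs) {
    member <- sampled[vapply(lab, function(x)
      L %in% rootPath(nomenclature, x), TRUE)]
    if (!length(member)) next
    node <- treeMRCA(tree, member)
    for (clock in clocks) {
      r <- computeRho(tree, clock, ref, clade = node)
      rows[[length(rows) + 1L]] <-
        data.frame(clade = L, n = r$n, rho = r$rho, sigma = r$sigma,
                   clock = clock@id,
                   age_ky = r$rho * clock@yearsPerMutation / 1000,
                   ci_low_ky = max(0, (r$rho - r$sigma) *
                                        clock@yearsPerMutation / 1000),
                   ci_high_ky = (r$rho + r$sigma) *
                     clock@yearsPerMutation / 1000,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$clade, out$clock), , drop = FALSE]
  rownames(out) <- NULL
  out
}
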