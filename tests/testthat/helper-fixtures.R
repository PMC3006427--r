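## shared fixtures, loaded once per test run

mtRef <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadReference()
    cache
  }
})

mtNom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadNomenclature()
    cache
  }
})

## an alternative base at np of the requested mutation class
altFor <- function(ref, np, class = c("transition", "transversion")) {
  class <- match.arg(class)
  rb <- refBase(ref, np)
  partners <- c(A = "G", G = "A", C = "T", T = "C")
  if (class == "transition") unname(partners[rb])
  else setdiff(c("A", "C", "G", "T"), c(rb, partners[rb]))[1]
}

## n random transition names (bare np) at distinct positions
randomTransitionNames <- function(n, exclude = integer()) {
  pool <- setdiff(seq_len(16569L), c(3107L, exclude))
  as.character(sample(pool, n))
}

## random binary-character parsimony instance: list(profiles, root)
randomParsimonyCase <- function(nHap, nChars) {
  sites <- as.character(sample(100:16000, nChars))
  profiles <- replicate(nHap, sites[runif(nChars) < 0.5], simplify = FALSE)
  names(profiles) <- paste0("H", seq_len(nHap))
  root <- sites[runif(nChars) < 0.2]
  list(profiles = profiles, root = root)
}

## independent minimum parsimony score via phangorn branch and bound
phangornMinScore <- function(profiles, root) {
  sets <- c(list(ROOT = root), profiles)
  all <- sort(unique(unlist(sets)))
  if (!length(all)) return(0L)
  if (length(sets) <= 3L) {
    ## any binary character on a <= 3-leaf tree costs 1 iff it varies
    varying <- Filter(function(s) {
      pres <- vapply(sets, function(p) s %in% p, TRUE)
      any(pres) && !all(pres)
    }, all)
    return(length(varying))
  }
  m <- do.call(rbind, lapply(sets, function(s) as.integer(all %in% s)))
  rownames(m) <- names(sets)
  ## phangorn needs variation; constant columns cost nothing either way
  pd <- phangorn::phyDat(m, type = "USER", levels = c(0L, 1L))
  trees <- phangorn::bab(pd, trace = 0)
  if (inherits(trees, "phylo")) trees <- c(trees)
  min(phangorn::parsimony(trees, pd))
}
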