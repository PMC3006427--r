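## Population frequency tables and HVS1 motif surveys.

#' Haplogroup frequencies by population
#'
#' Aggregates haplogroup assignments at a chosen nomenclature depth: each
#' sample is counted under its assignment's ancestor at that depth (or
#' under the assignment itself when it is shallower). Frequencies are
#' counts divided by the population sample size.
#'
#' @param assignments A `data.frame` as returned by [assignHaplogroups()]
#'   (columns `sample_id`, `population`, `haplogroup` required).
#' @param tree A [HaploNomenclature-class] object.
#' @param level Integer nomenclature depth at which to aggregate (root =
#'   0); e.g. level 1 aggregates every C subclade into C.
#' @return A `data.frame` with one row per (population, label): columns
#'   `population`, `haplogroup`, `n_sampled`, `count`, `frequency`.
#' @export
frequencyTable <- function(assignments, tree, level = 1L) {
  if (!nrow(assignments))
    return(data.frame(population = character(), haplogroup = character(),
                      n_sampled = integer(), count = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  bad <- setdiff(unique(assignments$haplogroup), nodeLabels(tree))
  if (length(bad))
    stop("unknown haplogroup label(s): ", paste(bad, collapse = ", "))
  atLevel <- vapply(assignments$haplogroup, function(lab) {
    p <- rootPath(tree, lab)
    p[min(length(p), level + 1L)]
  }, "")
  nPop <- table(assignments$population)
  tab <- aggregate(list(count = rep(1L, nrow(assignments))),
                   by = list(population = assignments$population,
                             haplogroup = atLevel), FUN = sum)
  tab$n_sampled <- as.integer(nPop[tab$population])
  tab$frequency <- tab$count / tab$n_sampled
  tab <- tab[order(tab$population, tab$haplogroup),
             c("population", "haplogroup", "n_sampled", "count", "frequency")]
  rownames(tab) <- NULL
  tab
}

#' Survey an HVS1 database for a diagnostic motif
#'
#' Counts, per population, the profiles whose variant set contains every
#' marker of the motif (containment matching: private extra variants do
#' not prevent a match; set `exact = TRUE` for strict equality). All motif
#' positions must lie within the HVS1 span (nps 16024--16383).
#'
#' @param db A [HaploProfiles-class] object with `coverage == "hvs1"`
#'   profiles.
#' @param motif Character vector of canonical variant names (e.g.
#'   `c("16093","16173","16223","16319","16362")`).
#' @param exact Require the variant set to equal the motif exactly.
#' @param ignore Variant names excluded from matching on both sides
#'   (default none: hypervariable positions are not auto-ignored).
#' @return A `data.frame` with one row per population: `population`,
#'   `region`, `n_sampled`, `count`, `frequency`.
#' @export
motifSurvey <- function(db, motif, exact = FALSE, ignore = character()) {
  if (any(db@info$coverage != "hvs1"))
    stop("motif surveys run on HVS1 databases (coverage 'hvs1')")
  motif <- setdiff(unique(as.character(motif)), ignore)
  if (length(motif) && any(!inHVS1(variantNp(motif))))
    stop("not an HVS1 motif: positions outside nps ",
         HVS1_SPAN[1], "-", HVS1_SPAN[2])
  hit <- vapply(db@variants, function(v) {
    v <- setdiff(v, ignore)
    if (exact) setequal(v, motif) else all(motif %in% v)
  }, TRUE)
  pops <- unique(db@info[, c("population", "region")])
  out <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    sel <- db@info$population == pops$population[i]
    data.frame(population = pops$population[i], region = pops$region[i],
               n_sampled = sum(sel), count = sum(hit & sel),
               frequency = sum(hit & sel) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$population), , drop = FALSE]
  rownames(out) <- NULL
  out
}
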