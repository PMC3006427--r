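---
title: "Dating mtDNA haplogroup expansions with mitophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating mtDNA haplogroup expansions with mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

## The problem

Human mitochondrial DNA is inherited maternally without recombination, so
the worldwide mtDNA pool forms a single genealogy whose named clades —
haplogroups — are defined by diagnostic mutation motifs relative to the
revised Cambridge Reference Sequence (rCRS). Population geneticists use
complete mtDNA genomes to (i) place each sampled individual into the
finest haplogroup whose motif it carries, (ii) reconstruct the
most-parsimonious mutation tree within a haplogroup, and (iii) estimate
when each clade began to expand, by converting the average mutational
distance from the clade's founder haplotype into calendar years with a
molecular clock. `mitophylo` implements this pipeline end to end, together
with a sequence simulator that provides ground truth for every stage.

## The rho statistic and its standard error

For a clade with $n$ sampled individuals whose root (founder) haplotype is
known, the rho statistic is the average number of counted mutations
separating each sample from the root:

$$\rho = \frac{1}{n}\sum_{i=1}^{n} d_i,$$

where $d_i$ is the number of counted mutation events on the tree path from
the clade root to sample $i$ (identical sampled haplotypes enter with
their multiplicity). Its standard error follows the branch-structure
estimator

$$\sigma^2 = \frac{1}{n^2}\sum_{b} \ell_b\, n_b^2,$$

summing over the branches $b$ of the clade, with $\ell_b$ counted events
on the branch and $n_b$ sampled descendants below it. For a star genealogy
this collapses to $\sigma = \sqrt{\rho/n}$, which the test suite verifies
automatically on random star clades.

Two linear clock calibrations are built in:

* **complete-genome clock** — every post-filter substitution counts, at
  one mutation per 3,624 years;
* **synonymous clock** — only substitutions that are synonymous under the
  vertebrate mitochondrial genetic code count, at one mutation per 7,884
  years.

The conversion is strictly linear, `age = rho * yearsPerMutation`, with a
one-sigma error range floored at zero. A nonlinear, selection-corrected
calibration is deliberately not implemented: only the two linear rates are
part of the model, and published interval estimates produced with a
nonlinear calibration will therefore not be matched exactly — only the
central ages are comparable. Point indels and transversions falling in the
two poly-C hotspot windows (nps 16180--16193 and 303--315) are excluded
before tree building and counting, mirroring standard practice;
transitions in those windows are retained. Whether indels *outside* the
windows are also excluded is a documented flag
(`excludeIndelsEverywhere`), off by default. Indels never count as clock
events under either calibration.

How tree events are counted: parallel mutations count separately each time
they occur, and a back mutation counts as one event; under the synonymous
clock a back-mutation event is classified by the site change it reverts.

## Functional classification

`classifySubstitution()` assigns each substitution to synonymous,
nonsynonymous, tRNA, rRNA, control-region or intergenic status using the
bundled annotation and `Biostrings`' vertebrate mitochondrial genetic
code. Three design choices matter:

* **Overlapping protein genes** (ATP8/ATP6, ND4L/ND4, and the single
  shared base of ATP6/CO3): every covering gene is evaluated and the most
  severe call wins (nonsynonymous over synonymous); the per-gene calls are
  retained in a `details` column. A change only counts as synonymous for
  the synonymous clock if it is synonymous in *every* covering protein
  gene. This is conservative: it never lets a change that alters some
  protein masquerade as neutral.
* **Incomplete stop codons.** Several genes end in a 1--2-nt codon
  completed by polyadenylation. Substitutions there are classified
  `coding_terminal` and never count as synonymous, avoiding invented
  amino-acid calls.
* **The light-strand gene** (ND6) is translated on its coding strand
  (reverse complement), as are the light-strand tRNAs for interval
  classification.

Sites in tRNA, rRNA and the control region are excluded from the
synonymous count: the synonymous clock counts synonymous coding changes
only. This is an assumption — the counting regime for RNA and
control-region changes under a "synonymous" rate is not uniquely
determined — and it is the same choice a strict synonymous-only counting
makes.

## Haplogroup assignment

The nomenclature is a rooted tree of labels, each carrying the variants
that define it relative to its parent, plus optional *negative markers*
(variants that must be absent; e.g. C4e requires the absence of the
2232.1A insertion that defines its sister clade C4a'b'c). The bundled
fixture encodes the haplogroup C and D clades whose motifs the source data
state explicitly; backbone clades whose full motifs are not stated carry
empty defining sets and are marked `placeholder`.

Because placeholders make raw tree depth meaningless, "most derived match"
is measured by the number of diagnostic markers matched, not by depth.
Among equally good nodes on one lineage the shallowest (least committed)
label is returned; equally good nodes on different lineages resolve to
their most recent common ancestor with an ambiguity flag. HVS1-only
profiles are matched on markers inside the HVS1 span (nps 16024--16383)
only. Matching is motif-exact by default; an `allowMissing` option
tolerates a bounded number of missing markers for real-world data with
private back mutations, and is off by default.

## Maximum-parsimony trees

Haplotypes are binary presence/absence vectors over variant names, rooted
at a supplied ancestral haplotype (normally a haplogroup's cumulative
motif). The search has three regimes:

1. **Perfect-phylogeny kernel.** When the derived-carrier sets of all
   variant sites form a laminar family (no incompatibility), the unique
   perfect phylogeny is built directly. This is the common case for
   within-haplogroup complete-genome data.
2. **Exhaustive search** over all rooted topologies for up to 8 distinct
   haplotypes (root included), scored by Fitch's algorithm, which is exact
   for binary characters.
3. **Stepwise addition + NNI hill climbing** above the bound, in a fixed
   taxon order (haplotype keys sorted lexicographically), so results are
   reproducible without any random number use.

Among equally parsimonious trees the search prefers the labelling with the
fewest reversions, computed by a Sankoff-style dynamic program with
lexicographic cost (total events, loss events), then the first topology in
enumeration order. This matches the drawing convention of mtDNA trees, in
which recurrent sites appear as parallel mutations (marked `<`) rather
than gain-plus-reversion chains; events that do restore the reference
state are marked as back mutations (`!`, the underline convention of
published figures). Identical sampled haplotypes collapse into one node
whose multiplicity records the number of individuals.

The test suite checks the search against an independent branch-and-bound
implementation (`phangorn::bab`) on hundreds of randomised instances, and
checks the perfect-phylogeny route on simulated infinite-sites data, where
the score must equal the number of segregating sites.

## The simulator and what it does (not) emulate

`simulateDataset()` generates sequences with known ground truth:
genealogies are either stars with all tips at a chosen TMRCA, Kingman
coalescent trees (via `ape::rcoal`, scaled so one coalescent unit equals
the configured time scale), or user-supplied time trees. Mutations are
Poisson on branch lengths at the clock's rate; sites are drawn
hotspot-weighted; transitions outweigh transversions 20:1 by default, the
order observed in human mtDNA. Under the synonymous clock, candidate sites
are restricted to changes the reference annotation marks as synonymous, so
the 7,884-year calibration is testable end to end. Infinite-sites mode
(default) never hits a site twice, cleanly separating estimator behaviour
from homoplasy handling; finite-sites mode generates deliberate parallel
and back mutations for the parsimony tests.

The default study conditions used by the recovery suites are star
genealogies with `n = 100` samples, TMRCAs of 5, 10 and 20 ky, and 200
replicates per condition; the whole pipeline (score, tree, rho, clock)
must recover the simulated TMRCA within three Monte-Carlo standard errors
with relative bias below 5%.

What the simulator does **not** emulate: rate heterogeneity among sites
beyond user-specified hotspots, selection, heteroplasmy, sequencing error,
indel mutation, and population structure or migration. Passing recovery
tests therefore demonstrates that the estimators are correctly implemented
and calibrated under the stated mutation model — not that real data meet
that model.

## The bundled reference

The package cannot redistribute the rCRS sequence itself, so it bundles a
clearly labelled *synthetic* stand-in (`synthetic_rcrs.fasta`), generated
deterministically by `syntheticReferenceSequence()`: the exact rCRS length
of 16,569 bp, the historical placeholder `N` at position 3107 (never
reported as a variant site), human-mtDNA-like base composition, and
repaired protein reading frames under the standard annotation (real
published gene coordinates, bundled as `mt_annotation.tsv`). Every
coordinate-dependent rule — motif positions, codon arithmetic, strand
handling, exclusion windows — is exact; only the base identities are
synthetic. Analyses of real sequences should supply the true rCRS FASTA to
`loadReference()`; everything downstream is unchanged.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed intervals in rCRS numbering throughout.
* Sequences of exactly 16,569 characters are diffed positionally;
  length-changed near-reference sequences go through
  `alignToReference()` (global alignment, indels normalised to the lowest
  possible position). Arbitrary divergent alignment is out of scope.
* A profile with two states at one position is rejected (haploid model).
* An empty profile assigns to the nomenclature root with an explicit
  `assigned = FALSE` flag; a clade with no sampled members cannot be
  dated (`computeRho()` errors rather than returning 0/0).
* `rho = 0` converts to age 0 with interval [0, 0]; negative inputs are
  errors.
* All randomised operations take explicit integer seeds and restore the
  caller's RNG state; the genealogy uses `seed` and sequence evolution
  `seed + 1`, so one configuration fully determines a dataset.

## Problem sizes used by the checks

The routine test suite runs the parsimony search against the
branch-and-bound oracle on 500 random instances of up to 6 haplotypes,
verifies the score-to-sequence round trip on 200 simulated genomes, and
runs the three 200-replicate recovery conditions described above; these
sizes keep the whole suite deterministic and reproducible on a single
CPU. The acceptance script (`scripts/acceptance.R`) rebuilds the two
clock-calibration fixtures from scratch at run time and reports the ages
they imply.

## Known limitations

* The nomenclature fixture encodes only the clades of haplogroups C and D
  with explicitly stated motifs plus a minimal backbone; it is not a
  complete mtDNA nomenclature and does not synchronise with external
  databases.
* Median networks with reticulations, bootstrap supports, and
  likelihood/Bayesian dating are out of scope; the parsimony criterion is
  the only optimality criterion implemented.
* CI bounds are symmetric one-sigma intervals on the linear scale;
  published asymmetric intervals derived from nonlinear calibrations are
  not reproduced.
* The stepwise+NNI regime above the exhaustive bound is a heuristic: it
  is deterministic and near-minimal in practice, but only the exhaustive
  regime carries an optimality guarantee.
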