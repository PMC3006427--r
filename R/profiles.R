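## Sample profiles: construction and the variant-list text format.

#' Construct a set of sequence profiles
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param variants List of character vectors of canonical variant names,
#'   one per sample (a single character vector is accepted for one sample).
#' @param population Population name(s), recycled.
#' @param region Geographic region, one of `"northeastern_asia"`,
#'   `"central_southern_siberia"`, `"eastern_asia"`, `"india"`, `"europe"`,
#'   `"other"`; recycled.
#' @param coverage `"complete"` or `"hvs1"`; recycled. HVS1 profiles may
#'   only contain variants within nps 16024--16383.
#' @return A [HaploProfiles-class] object.
#' @examples
#' HaploProfiles("S1", list(c("16093", "16223")), coverage = "hvs1")
#' @export
HaploProfiles <- function(sample_id, variants, population = "unknown",
                          region = "other", coverage = "complete") {
  if (is.character(variants)) variants <- list(variants)
  n <- length(sample_id)
  info <- data.frame(sample_id = as.character(sample_id),
                     population = rep_len(population, n),
                     region = rep_len(region, n),
                     coverage = rep_len(coverage, n),
                     stringsAsFactors = FALSE)
  new("HaploProfiles", info = info,
      variants = lapply(variants, as.character))
}

#' Accessors for HaploProfiles
#'
#' `sampleInfo()` returns the metadata table; `profileVariants()` the list
#' of variant sets (optionally for a subset of samples); `nSamples()` the
#' number of profiles.
#'
#' @param x A [HaploProfiles-class] object.
#' @param sample_id Optional character vector restricting the result.
#' @return See each description.
#' @export
sampleInfo <- function(x) x@info

#' @rdname sampleInfo
#' @export
profileVariants <- function(x, sample_id = NULL) {
  v <- setNames(x@variants, x@info$sample_id)
  if (is.null(sample_id)) v else v[sample_id]
}

#' @rdname sampleInfo
#' @export
nSamples <- function(x) nrow(x@info)

#' Read and write variant-list profile tables
#'
#' The variant-list format is a tab-separated text file with a header and
#' one sample per line:
#' `sample_id  population  region  coverage  variants`, where `variants` is
#' a comma-separated list of canonical variant names (`.` for none).
#'
#' @param file Path to the file.
#' @param x A [HaploProfiles-class] object.
#' @return `readProfileTable()` returns a [HaploProfiles-class] object;
#'   `writeProfileTable()` returns `file` invisibly.
#' @export
readProfileTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population", "region", "coverage", "variants")
  if (!all(need %in% names(d)))
    stop("profile table must have columns ", paste(need, collapse = ", "))
  vars <- lapply(d$variants, function(v) {
    if (is.na(v) || v %in% c("", ".")) character() else
      strsplit(v, ",", fixed = TRUE)[[1]]
  })
  new("HaploProfiles",
      info = d[, c("sample_id", "population", "region", "coverage")],
      variants = vars)
}

#' @rdname readProfileTable
#' @export
writeProfileTable <- function(x, file) {
  d <- x@info
  d$variants <- vapply(x@variants, function(v)
    if (length(v)) paste(v, collapse = ",") else ".", "")
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export profiles as a minimal VCF
#'
#' Writes the union of all sample variants as a minimal VCF 4.2 file
#' against the rCRS-numbered reference (contig `chrM`), with one haploid
#' genotype column per sample. Indels are written with the usual
#' anchor-base convention.
#'
#' @param x A [HaploProfiles-class] object.
#' @param ref An [MtReference-class] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeVariantVCF <- function(x, ref, file) {
  allNames <- sort(unique(unlist(x@variants)))
  seqChars <- refCharVec(ref)
  rows <- lapply(allNames, function(nm) {
    v <- parseVariants(nm, ref)
    if (v$mclass %in% c("transition", "transversion")) {
      c(pos = v$np, ref = v$ref, alt = v$alt)
    } else if (v$mclass == "deletion") {
      c(pos = v$np - 1L, ref = paste0(seqChars[v$np - 1L], v$ref),
        alt = seqChars[v$np - 1L])
    } else {  # insertion
      c(pos = v$np, ref = seqChars[v$np],
        alt = paste0(seqChars[v$np], v$alt))
    }
  })
  gt <- vapply(x@variants, function(v) as.integer(allNames %in% v),
               integer(length(allNames)))
  gt <- matrix(gt, nrow = length(allNames))
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=chrM,length=%d>", MT_LENGTH),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x@info$sample_id), collapse = "\t"))
  body <- vapply(seq_along(allNames), function(i) {
    paste(c("chrM", rows[[i]][["pos"]], allNames[i], rows[[i]][["ref"]],
            rows[[i]][["alt"]], ".", ".", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(lines, body), file)
  invisible(file)
}
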