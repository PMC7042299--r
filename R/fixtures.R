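# Accessors for the packaged reference fixtures under inst/extdata.

famprio_extdata <- function(file) {
  p <- system.file("extdata", file, package = "famprio")
  if (p == "") stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' Established-variant lookup table
#'
#' Variants previously described in familial MDS/AML; a hit here classifies
#' a known-locus variant as pathogenic outright in
#' [assess_known_variant()].
#'
#' @param path optional TSV with `gene`, `hgvs_c`, `hgvs_p` (defaults to
#'   the packaged table).
#' @return tibble.
#' @export
known_variant_db <- function(path = NULL) {
  readr::read_tsv(path %||% famprio_extdata("known_variants.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' The three published constitutional RUNX1 deletions
#'
#' Breakpoints of the germline RUNX1 deletions found in three familial
#' platelet disorder / AML families, as 1-based inclusive chr21 intervals.
#' Two coordinate pairs are on record for family FML031 (the array call and
#' an alternative reported pair); the array set is the default for the
#' common-segment computation, and the intersection is identical under
#' either since neither FML031 pair attains the maximal start or minimal
#' end.
#'
#' @param fml031 which FML031 coordinate pair to use: `"array"` (default)
#'   or `"report"`.
#' @return tibble with `chrom`, `start`, `end`, `label` — ready for
#'   [intersect_intervals()].
#' @export
runx1_deletions <- function(fml031 = c("array", "report")) {
  fml031 <- match.arg(fml031)
  tab <- readr::read_tsv(famprio_extdata("runx1_deletions.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  tab <- tab[tab$label != "FML031" | tab$set == fml031, ]
  tab[c("chrom", "start", "end", "label")]
}

#' Synthetic RUNX1 promoter/exon feature model
#'
#' Illustrative (synthetic) coordinates for the distal RUNX1 promoter and
#' first exons, laid out so that their position relative to the common
#' deleted segment matches the published description; real exon coordinates
#' are not part of the packaged data.
#'
#' @return tibble with `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
runx1_features <- function() {
  read_bed(famprio_extdata("runx1_features_synthetic.bed"))
}

#' External candidate-gene lists for cross-reference rescue
#'
#' Gene symbols from prior familial MDS/AML and inherited bone-marrow-
#' failure discovery series, used by [rescue_by_cross_reference()]. The
#' packaged lists are the illustrative subsets referenced in this
#' package's analyses (one symbol per line).
#'
#' @param dir optional directory of `*.txt` list files (file name minus
#'   extension becomes the list name).
#' @return named list of character vectors.
#' @export
external_candidate_lists <- function(dir = NULL) {
  dir <- dir %||% famprio_extdata("external_lists")
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no candidate list files in ", dir, call. = FALSE)
  out <- lapply(files, function(f) {
    x <- trimws(readLines(f))
    x[nzchar(x) & !startsWith(x, "#")]
  })
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}

#' Genes recurrently mutated in sporadic AML
#'
#' Symbols reported mutated in sporadic AML series (TCGA-LAML and the
#' BeatAML cohort), used to annotate candidate-gene overlap.
#'
#' @param path optional file, one symbol per line.
#' @return character vector.
#' @export
sporadic_aml_genes <- function(path = NULL) {
  x <- trimws(readLines(path %||% famprio_extdata("sporadic_aml_genes.txt")))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Packaged 86-family example cohort
#'
#' A cohort reproducing the published totals of the familial MDS/AML series
#' (86 families; 221 individuals of whom 168 affected and 53 unaffected;
#' phenotype category counts 12/17/18/15/24). Family structures and
#' individual-level details are illustrative.
#'
#' @return a `fam_cohort`.
#' @export
example_cohort <- function() {
  read_pedigree(famprio_extdata("familial_cohort.ped"),
                famprio_extdata("familial_cohort_phenotypes.tsv"))
}

#' Packaged per-family known-locus call fixture
#'
#' One row per family with the gene and pathogenicity category of its best
#' known-locus finding (`category = "none"` for molecularly unexplained
#' families). Tier totals follow the published cohort classification
#' (39 high-evidence + 4 moderate + 6 emerging explained families, 37
#' unexplained); the per-gene assignment within tiers is illustrative.
#' Feeding this through [assign_family_groups()] reproduces the cohort's
#' Group 1 / Group 2 split.
#'
#' @return tibble with `family_id`, `gene`, `tier`, `category`.
#' @export
known_locus_calls <- function() {
  readr::read_tsv(famprio_extdata("known_locus_families.tsv"),
                  show_col_types = FALSE, progress = FALSE)
}
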