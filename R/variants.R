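# Annotated germline variant handling: VCF + annotation TSV loading, VAF,
# HGVS consequence classification, the exome pre-filter, and the 2-of-4
# in-silico predictor consensus.

CONSEQUENCE_LEVELS <- c("missense", "nonsense", "frameshift_indel",
                        "inframe_indel", "splice_proximal", "start_lost",
                        "synonymous", "other")

PREDICTOR_COLS <- c("polyphen2", "mutation_taster", "sift", "provean")

#' Variant allele fraction from read depths
#'
#' Germline heterozygous variants are expected near `vaf = 0.5`; the
#' prioritization criteria require `vaf > 0.30` to call a variant
#' germline-range (strict inequality: exactly 0.30 fails).
#'
#' @param alt_depth reads supporting the alternate allele.
#' @param depth total read depth.
#' @return `alt_depth / depth`, or `NA` where `depth == 0`.
#' @examples
#' compute_vaf(30, 62)
#' @export
compute_vaf <- function(alt_depth, depth) {
  if (any(alt_depth < 0, na.rm = TRUE) || any(depth < 0, na.rm = TRUE)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  if (any(alt_depth > depth, na.rm = TRUE)) {
    stop("alt_depth exceeds depth", call. = FALSE)
  }
  ifelse(!is.na(depth) & depth == 0, NA_real_, alt_depth / depth)
}

#' Classify the functional consequence of a variant
#'
#' Classification follows HGVS notation first and falls back on the raw
#' annotation string. Protein-level changes ending in a stop (`X`, `*`,
#' `Ter`) are nonsense; `fs` indels are frameshift; `p.Met1?` is start-lost
#' (a loss-of-function class); intronic offsets of the form `c.N+k` /
#' `c.N-k` are splice-proximal with the signed offset parsed out (only
#' |offset| <= 3 later qualifies as a canonical splice-region hit); unchanged
#' protein is synonymous; residue substitutions are missense. Unparseable
#' input with no usable raw consequence is classified `other`.
#'
#' @param hgvs_c,hgvs_p HGVS coding / protein notation (either may be `NA`).
#' @param consequence_raw upstream annotation term (e.g. VEP), used as a
#'   fallback.
#' @return tibble with `consequence` and `splice_offset` (non-`NA` iff
#'   `consequence == "splice_proximal"`).
#' @examples
#' classify_consequence("c.258+2T>C", NA, NA)
#' classify_consequence("c.370C>T", "p.Arg124X", NA)
#' @export
classify_consequence <- function(hgvs_c, hgvs_p = NA, consequence_raw = NA) {
  n <- max(length(hgvs_c), length(hgvs_p), length(consequence_raw))
  hgvs_c <- rep_len(as.character(hgvs_c), n)
  hgvs_p <- rep_len(as.character(hgvs_p), n)
  raw <- rep_len(tolower(as.character(consequence_raw)), n)

  cls <- rep(NA_character_, n)
  off <- rep(NA_integer_, n)

  p <- gsub("^p\\.", "", ifelse(is.na(hgvs_p), "", hgvs_p))
  p <- gsub("\\s", "", p)

  is_fs <- grepl("fs", p)
  is_stop <- !is_fs & grepl("(Ter[0-9]*|X|\\*)$", p) & p != ""
  is_start <- !is_fs & !is_stop & grepl("^Met1\\?$", p)
  cls[is_fs] <- "frameshift_indel"
  cls[is_stop] <- "nonsense"
  cls[is_start] <- "start_lost"

  # splice-proximal: intronic offset in the coding HGVS
  cc <- ifelse(is.na(hgvs_c), "", gsub("\\s", "", hgvs_c))
  has_spl <- is.na(cls) & lengths(regmatches(cc, gregexpr(
    "c\\.[*-]?[0-9]+[+-][0-9]+", cc))) > 0
  if (any(has_spl)) {
    offs <- vapply(cc[has_spl], function(s) {
      mm <- regmatches(s, regexec("c\\.[*-]?[0-9]+([+-][0-9]+)", s))[[1]]
      as.integer(mm[2])
    }, integer(1))
    cls[has_spl] <- "splice_proximal"
    off[has_spl] <- offs
  }

  syn <- is.na(cls) & (p %in% c("(=)", "=") |
                         grepl("^([A-Z][a-z]{2})([0-9]+)\\1$", p, perl = TRUE) |
                         grepl("synonymous", raw))
  cls[syn] <- "synonymous"

  indel <- is.na(cls) & grepl("(del|ins|dup)", p)
  cls[indel] <- "inframe_indel"

  mis <- is.na(cls) & grepl("^[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}$", p)
  cls[mis] <- "missense"

  # fall back on the raw annotation term
  fb <- is.na(cls)
  cls[fb & grepl("missense", raw)] <- "missense"
  cls[fb & grepl("stop_gain|nonsense", raw)] <- "nonsense"
  cls[fb & grepl("frameshift", raw)] <- "frameshift_indel"
  cls[fb & grepl("inframe", raw)] <- "inframe_indel"
  cls[fb & grepl("start_lost|initiator", raw)] <- "start_lost"
  unparsed <- is.na(cls)
  if (any(unparsed)) {
    rlang::inform(sprintf(
      "%d variant(s) could not be classified from HGVS or raw consequence; set to 'other'",
      sum(unparsed)))
    cls[unparsed] <- "other"
  }
  tibble(consequence = cls, splice_offset = off)
}

#' Is a consequence in the loss-of-function class?
#'
#' Nonsense, frameshift, start-lost, and splice-proximal variants within
#' `max_offset` of the exon boundary.
#'
#' @param consequence,splice_offset as returned by [classify_consequence()].
#' @param max_offset largest qualifying |intronic offset| (default 3).
#' @export
is_lof_class <- function(consequence, splice_offset = NA, max_offset = 3) {
  consequence %in% c("nonsense", "frameshift_indel", "start_lost") |
    (consequence == "splice_proximal" &
       !is.na(splice_offset) & abs(splice_offset) <= max_offset)
}

#' Two-of-four in-silico predictor consensus
#'
#' A missense variant is supported when at least `min_damaging` of the four
#' predictors (PolyPhen2, MutationTaster, SIFT, Provean) call it damaging;
#' a missing call never counts as damaging. Loss-of-function-class variants
#' (and in-frame indels, which substitution-oriented predictors cannot
#' score) pass unconditionally unless `strict = TRUE`.
#'
#' @param predictors data frame with columns
#'   `polyphen2, mutation_taster, sift, provean`, each in
#'   `damaging`/`tolerated`/`missing`.
#' @param consequence,splice_offset consequence classification.
#' @param min_damaging consensus threshold (default 2).
#' @param strict apply the consensus to every class, including LoF.
#' @return logical vector.
#' @export
predictor_consensus <- function(predictors, consequence,
                                splice_offset = NA, min_damaging = 2,
                                strict = FALSE) {
  predictors <- as.data.frame(predictors)[PREDICTOR_COLS]
  n_dam <- Reduce(`+`, lapply(predictors, function(x) {
    as.integer(!is.na(x) & x == "damaging")
  }))
  pass <- n_dam >= min_damaging
  if (!strict) {
    exempt <- is_lof_class(consequence, splice_offset) |
      consequence == "inframe_indel"
    pass <- pass | exempt
  }
  unname(pass)
}

normalize_predictor <- function(x) {
  key <- tolower(trimws(as.character(x)))
  dam <- c("damaging", "deleterious", "d", "probably_damaging",
           "possibly_damaging", "disease_causing", "a")
  tol <- c("tolerated", "benign", "neutral", "t", "n", "polymorphism")
  out <- rep("missing", length(key))
  out[key %in% dam] <- "damaging"
  out[key %in% tol] <- "tolerated"
  out
}

#' Load annotated variant calls from a VCF and an annotation table
#'
#' Joins per-sample genotype calls (VCF with `AD`/`DP` per sample) to a
#' per-variant annotation TSV keyed by `chrom, pos, ref, alt`. Multi-allelic
#' records are decomposed into biallelic rows before the join. One output row
#' is emitted per variant x carrier; missing annotation values stay `NA`
#' (never silently 0). Records with no matching annotation row are dropped
#' with a warning and counted in the load report.
#'
#' The annotation TSV header is fixed: `chrom pos ref alt gene transcript
#' canonical hgvs_c hgvs_p consequence exac_af gnomad_af segdup polyphen2
#' mutation_taster sift provean` (optional extra columns, e.g.
#' `splice_impact`, are carried through).
#'
#' @param vcf_path VCF 4.x file.
#' @param annotation_path annotation TSV.
#' @param cohort optional `fam_cohort`; used to attach `family_id` to each
#'   carrier.
#' @return tibble of annotated variant x carrier rows with attribute
#'   `"load_report"` (record/row/annotation tallies).
#' @export
read_variants <- function(vcf_path, annotation_path, cohort = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF drops to vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = n_rec,
                                dimnames = list(NULL, names(x))) else x
  }
  gt <- as_mat(vcfR::extract.gt(vcf, element = "GT"))
  ad <- as_mat(vcfR::extract.gt(vcf, element = "AD"))
  dp <- as_mat(suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                                 as.numeric = TRUE)))
  samples <- colnames(gt)

  rows <- list()
  n_biallelic <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    n_biallelic <- n_biallelic + length(alts)
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g)) next
      alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
      ad_vec <- suppressWarnings(
        as.integer(strsplit(ad[i, j], ",", fixed = TRUE)[[1]]))
      for (k in seq_along(alts)) {
        if (!as.character(k) %in% alleles) next
        alt_d <- if (length(ad_vec) >= k + 1) ad_vec[k + 1] else NA_integer_
        d <- dp[i, j]
        if (is.na(d) && !anyNA(ad_vec)) d <- sum(ad_vec)
        rows[[length(rows) + 1L]] <- tibble(
          chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref = fix$REF[i],
          alt = alts[k],
          carrier_id = samples[j],
          depth = as.integer(d),
          alt_depth = alt_d
        )
      }
    }
  }
  calls <- if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), carrier_id = character(),
           depth = integer(), alt_depth = integer())

  anno <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene")
  if (!all(need %in% names(anno))) {
    stop("annotation table must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  anno$chrom <- as.character(anno$chrom)
  anno$pos <- as.integer(anno$pos)
  for (col in PREDICTOR_COLS) {
    anno[[col]] <- if (col %in% names(anno))
      normalize_predictor(anno[[col]]) else "missing"
  }
  if (!"canonical" %in% names(anno)) anno$canonical <- TRUE
  anno$canonical <- isTRUE_vec(anno$canonical)
  if (!"segdup" %in% names(anno)) anno$segdup <- FALSE
  anno$segdup <- isTRUE_vec(anno$segdup)
  for (col in c("exac_af", "gnomad_af")) {
    anno[[col]] <- if (col %in% names(anno))
      suppressWarnings(as.numeric(anno[[col]])) else NA_real_
  }
  if (!"consequence" %in% names(anno)) anno$consequence <- NA_character_
  for (col in c("hgvs_c", "hgvs_p", "transcript")) {
    if (!col %in% names(anno)) anno[[col]] <- NA_character_
  }
  names(anno)[names(anno) == "consequence"] <- "consequence_raw"

  joined <- inner_join(calls, anno, by = c("chrom", "pos", "ref", "alt"),
                       relationship = "many-to-one")
  n_unmatched <- nrow(calls) - nrow(joined)
  if (n_unmatched > 0) {
    warning(sprintf(
      "%d call row(s) had no annotation entry and were excluded", n_unmatched),
      call. = FALSE)
  }

  joined$vaf <- compute_vaf(joined$alt_depth, joined$depth)
  joined$note <- ifelse(is.na(joined$vaf) &
                          (!is.na(joined$depth) & joined$depth == 0),
                        "no_depth", NA_character_)
  cls <- classify_consequence(joined$hgvs_c, joined$hgvs_p,
                              joined$consequence_raw)
  joined <- bind_cols(joined, cls)
  joined$variant_id <- paste(joined$chrom, joined$pos, joined$ref,
                             joined$alt, sep = ":")
  joined$family_id <- if (!is.null(cohort)) {
    cohort$members$family_id[match(joined$carrier_id,
                                   cohort$members$individual_id)]
  } else NA_character_

  attr(joined, "load_report") <- tibble(
    records = n_rec,
    biallelic_rows = n_biallelic,
    carrier_rows = nrow(calls),
    annotated = nrow(joined),
    unannotated = n_unmatched
  )
  joined
}

#' Exome pre-filter: rarity, depth, segmental duplications
#'
#' Keeps variants that are rare (external allele frequency `< af_max` in both
#' ExAC and gnomAD, or absent from them), adequately covered
#' (`depth >= min_depth`), and outside segmentally duplicated regions.
#' A missing population frequency passes the frequency rule (absence from the
#' reference databases is evidence of rarity, not of commonness). The filter
#' is idempotent.
#'
#' @param variants tibble of annotated variants (see [read_variants()]).
#' @param af_max external allele frequency threshold (default 0.005).
#' @param min_depth minimum read depth (default 20).
#' @return filtered tibble; per-rule exclusion counts (evaluated
#'   independently) in attribute `"exclusions"`.
#' @export
prefilter_variants <- function(variants, af_max = 0.005, min_depth = 20) {
  v <- as_tibble(variants)
  freq_ok <- (is.na(v$exac_af) | v$exac_af < af_max) &
    (is.na(v$gnomad_af) | v$gnomad_af < af_max)
  depth_ok <- !is.na(v$depth) & v$depth >= min_depth
  segdup_ok <- !isTRUE_vec(v$segdup)
  keep <- freq_ok & depth_ok & segdup_ok
  out <- v[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble(
    rule = c("frequency", "depth", "segdup"),
    n_excluded = c(sum(!freq_ok), sum(!depth_ok), sum(!segdup_ok))
  )
  attr(out, "sim_id") <- attr(variants, "sim_id", exact = TRUE)
  out
}
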