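# The exome discovery cascade for molecularly unexplained (Group 2)
# families: per-variant criteria, gene-level cross-family recurrence with a
# stricter rule for missense-only genes, rescue by cross-reference against
# external candidate lists, the synonymous splice-impact scan, sporadic-AML
# overlap annotation, and the orchestrating pipeline.

#' Discovery cascade configuration
#'
#' Thresholds for the per-variant criteria and the gene-level recurrence
#' rules. Defaults follow the published cascade: germline-range VAF
#' (> 0.30, strict), canonical-transcript consequences restricted to
#' missense, indels, nonsense, start-lost and splice-region hits within
#' three bases of the exon boundary, ExAC frequency below 1e-4 (or absent),
#' 2-of-4 predictor consensus for missense, and gene inclusion when
#' loss-of-function-class variants recur in two or more families, mixed
#' LoF+missense support reaches two families, or missense-only support
#' reaches three or more families (the stricter rule that mitigates the
#' dominance of missense calls, 86.3% of rare coding variants).
#'
#' @param vaf_min minimum VAF, strict (default 0.30).
#' @param exac_max maximum ExAC allele frequency for criterion (iv)
#'   (default 1e-4; absent passes).
#' @param splice_offset_max largest qualifying |intronic offset| (default 3).
#' @param predictors_min predictor consensus threshold (default 2).
#' @param strict_predictors apply the consensus to LoF-class variants too.
#' @param lof_family_min families with LoF-class variants needed for
#'   inclusion (default 2).
#' @param mixed_family_min total families needed when LoF and missense
#'   support mix (default 2).
#' @param missense_family_min families needed for missense-only genes
#'   (default 3).
#' @param prefilter_af_max,min_depth pre-filter settings (see
#'   [prefilter_variants()]).
#' @param chip_genes genes whose variants carry a clonal-hematopoiesis
#'   caution flag.
#' @param synonymous_splice_threshold minimum splice-impact score for the
#'   synonymous scan.
#' @param strict_segregation see [assess_segregation()].
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(vaf_min = 0.30, exac_max = 1e-4,
                             splice_offset_max = 3, predictors_min = 2,
                             strict_predictors = FALSE,
                             lof_family_min = 2, mixed_family_min = 2,
                             missense_family_min = 3,
                             prefilter_af_max = 0.005, min_depth = 20,
                             chip_genes = c("TET2", "DNMT3A", "ASXL1"),
                             synonymous_splice_threshold = 0.5,
                             strict_segregation = FALSE) {
  structure(as.list(environment()), class = "discovery_config")
}

QUALIFYING_CLASSES <- c("missense", "nonsense", "frameshift_indel",
                        "inframe_indel", "start_lost", "splice_proximal")

#' Apply the per-variant discovery criteria (i)-(v)
#'
#' Keeps variants that (i) show a germline-range VAF (> `vaf_min`), (ii)
#' are missense, indel, nonsense, start-lost or splice-region (within
#' `splice_offset_max` of the exon boundary) changes on the canonical
#' transcript, (iii) are not refuted by segregation where testing was
#' possible (untestable variants pass; families with material on the index
#' case only are retained), (iv) are rare in population controls (ExAC
#' `< exac_max` or absent), and (v) reach the in-silico predictor consensus
#' (missense only, unless `strict_predictors`). Inputs are expected to have
#' passed [prefilter_variants()].
#'
#' @param variants annotated variant x carrier tibble.
#' @param seg_status optional tibble from [segregation_table()]
#'   (`variant_id`, `family_id`, `status`); variants with no entry are
#'   treated as untestable.
#' @param config a [discovery_config()].
#' @return the retained rows, with attribute `"criteria_exclusions"`: an
#'   independent per-criterion exclusion tally.
#' @export
apply_variant_criteria <- function(variants, seg_status = NULL,
                                   config = discovery_config()) {
  v <- as_tibble(variants)
  if (!nrow(v)) {
    out <- v
    attr(out, "criteria_exclusions") <- tibble(
      criterion = c("vaf", "consequence", "segregation", "frequency",
                    "predictors"),
      n_excluded = 0L)
    return(out)
  }
  vaf_ok <- !is.na(v$vaf) & v$vaf > config$vaf_min
  class_ok <- v$consequence %in% QUALIFYING_CLASSES &
    (v$consequence != "splice_proximal" |
       (!is.na(v$splice_offset) &
          abs(v$splice_offset) <= config$splice_offset_max)) &
    isTRUE_vec(v$canonical)
  if (!is.null(seg_status)) {
    st <- v |>
      left_join(seg_status[c("variant_id", "family_id", "status")],
                by = c("variant_id", "family_id"))
    seg <- st$status
  } else {
    seg <- rep(NA_character_, nrow(v))
  }
  n_missing_seg <- sum(is.na(seg))
  seg[is.na(seg)] <- "untestable"
  seg_ok <- seg != "refuted"
  freq_ok <- is.na(v$exac_af) | v$exac_af < config$exac_max
  pred_ok <- predictor_consensus(v[PREDICTOR_COLS], v$consequence,
                                 v$splice_offset,
                                 min_damaging = config$predictors_min,
                                 strict = config$strict_predictors)
  keep <- vaf_ok & class_ok & seg_ok & freq_ok & pred_ok
  out <- v[keep, , drop = FALSE]
  out$segregation_status <- seg[keep]
  attr(out, "criteria_exclusions") <- tibble(
    criterion = c("vaf", "consequence", "segregation", "frequency",
                  "predictors"),
    n_excluded = c(sum(!vaf_ok), sum(!class_ok), sum(!seg_ok),
                   sum(!freq_ok), sum(!pred_ok))
  )
  attr(out, "n_missing_segregation") <- n_missing_seg
  attr(out, "sim_id") <- attr(variants, "sim_id", exact = TRUE)
  out
}

#' Aggregate cross-family recurrence per gene (criterion vi)
#'
#' Recurrence counts families, not variants: two qualifying variants in one
#' family count once. A gene is included when loss-of-function-class
#' variants (nonsense, frameshift or in-frame indels, start-lost,
#' splice-region) occur in at least `lof_family_min` families
#' (`lof_recurrence`); when LoF and missense support together reach
#' `mixed_family_min` families with at least one LoF family
#' (`mixed_recurrence`); or when missense variants occur in at least
#' `missense_family_min` families (`missense_recurrence`).
#'
#' @param passing criteria-passing variants from [apply_variant_criteria()].
#' @param config a [discovery_config()].
#' @return tibble, one row per gene with family-id sets (`families_lof`,
#'   `families_missense`, `families_any` as list-columns), their sizes,
#'   `included` and `inclusion_reason`.
#' @export
aggregate_gene_recurrence <- function(passing, config = discovery_config()) {
  v <- as_tibble(passing)
  if (!nrow(v)) {
    return(tibble(gene = character(), families_lof = list(),
                  families_missense = list(), families_any = list(),
                  n_lof = integer(), n_missense = integer(),
                  n_any = integer(), included = logical(),
                  inclusion_reason = character()))
  }
  v$is_missense <- v$consequence == "missense"
  agg <- v |>
    group_by(.data$gene) |>
    summarise(
      families_lof = list(sort(unique(.data$family_id[!.data$is_missense]))),
      families_missense = list(sort(unique(.data$family_id[.data$is_missense]))),
      .groups = "drop"
    ) |>
    mutate(
      families_any = mapply(function(a, b) sort(union(a, b)),
                            .data$families_lof, .data$families_missense,
                            SIMPLIFY = FALSE),
      n_lof = lengths(.data$families_lof),
      n_missense = lengths(.data$families_missense),
      n_any = lengths(.data$families_any),
      inclusion_reason = dplyr::case_when(
        .data$n_lof >= config$lof_family_min ~ "lof_recurrence",
        .data$n_lof >= 1 &
          .data$n_any >= config$mixed_family_min ~ "mixed_recurrence",
        .data$n_missense >= config$missense_family_min ~ "missense_recurrence",
        TRUE ~ NA_character_
      ),
      included = !is.na(.data$inclusion_reason)
    ) |>
    arrange(.data$gene)
  agg
}

#' Rescue single-family genes by cross-reference with external series
#'
#' A gene that fails the recurrence rules but carries at least one
#' criteria-passing variant and appears in an external candidate list
#' (prior familial MDS/AML or inherited bone-marrow-failure series) is
#' included with reason `cross_reference_rescue`. Genes already included
#' are unchanged; listed genes with no passing variant are never rescued.
#'
#' @param aggregates output of [aggregate_gene_recurrence()].
#' @param passing the criteria-passing variants (used only to guarantee the
#'   >= 1 passing variant requirement, which the aggregates already encode).
#' @param lists named list of character vectors of gene symbols (see
#'   [external_candidate_lists()]).
#' @return aggregates with rescued genes included and a `rescue_source`
#'   column naming the matching list(s).
#' @export
rescue_by_cross_reference <- function(aggregates, passing, lists) {
  agg <- as_tibble(aggregates)
  if (!length(lists) || !nrow(agg)) {
    agg$rescue_source <- NA_character_
    return(agg)
  }
  src <- vapply(agg$gene, function(g) {
    hit <- names(lists)[vapply(lists, function(l) g %in% l, logical(1))]
    if (length(hit)) paste(hit, collapse = ",") else NA_character_
  }, character(1), USE.NAMES = FALSE)
  rescue <- !agg$included & agg$n_any >= 1 & !is.na(src)
  agg$included[rescue] <- TRUE
  agg$inclusion_reason[rescue] <- "cross_reference_rescue"
  agg$rescue_source <- ifelse(rescue, src, NA_character_)
  agg
}

#' Scan synonymous variants for predicted splice impact
#'
#' Synonymous variants are not part of the main cascade, but a synonymous
#' change can create or destroy a splice element. This scan returns novel
#' (absent from ExAC and gnomAD) synonymous variants whose upstream
#' splice-impact annotation exceeds `threshold`. The result is disjoint
#' from the main candidate list by construction (class filter).
#'
#' @param variants annotated variants carrying a `splice_impact` column
#'   (numeric score or logical flag) produced by upstream annotation.
#' @param threshold minimum score (default 0.5); logical flags are taken
#'   as-is.
#' @return the qualifying synonymous variant rows.
#' @export
scan_synonymous_splicing <- function(variants, threshold = 0.5) {
  v <- as_tibble(variants)
  if (!"splice_impact" %in% names(v)) {
    stop("variants carry no 'splice_impact' column; annotate with a splice-impact predictor first",
         call. = FALSE)
  }
  impact <- if (is.logical(v$splice_impact)) {
    isTRUE_vec(v$splice_impact)
  } else {
    !is.na(v$splice_impact) & v$splice_impact > threshold
  }
  v[v$consequence == "synonymous" & impact &
      is.na(v$exac_af) & is.na(v$gnomad_af), , drop = FALSE]
}

#' Annotate gene aggregates with sporadic-AML overlap
#'
#' @param aggregates output of [aggregate_gene_recurrence()] (possibly
#'   after rescue).
#' @param sporadic_genes character vector of genes reported mutated in
#'   sporadic AML (see [sporadic_aml_genes()]).
#' @return aggregates with a `sporadic_aml` flag; the percentage of
#'   included genes with sporadic overlap (nearest integer) is attached as
#'   attribute `"sporadic_overlap_pct"` (`NA` when nothing is included).
#' @export
annotate_sporadic_overlap <- function(aggregates, sporadic_genes) {
  agg <- as_tibble(aggregates)
  agg$sporadic_aml <- agg$gene %in% sporadic_genes
  n_incl <- sum(agg$included)
  attr(agg, "sporadic_overlap_pct") <- if (n_incl == 0) NA_real_ else
    round(100 * sum(agg$sporadic_aml & agg$included) / n_incl)
  agg
}

#' Run the full discovery cascade
#'
#' Orchestrates pre-filtering, segregation, the per-variant criteria, gene
#' recurrence aggregation, optional cross-reference rescue and sporadic-AML
#' annotation, and assembles the discovery report. Deterministic given its
#' inputs and configuration.
#'
#' @param cohort a `fam_cohort` of the discovery families.
#' @param variants annotated variant x carrier tibble (see
#'   [read_variants()] or [simulate_cohort()]).
#' @param genotypes optional long genotype table for segregation (see
#'   [segregation_table()]); without it every variant is untestable.
#' @param config a [discovery_config()].
#' @param external_lists optional named list of gene symbol vectors for
#'   rescue.
#' @param sporadic_genes optional sporadic-AML gene symbols.
#' @return a `fam_discovery` report: `variants_final`, `variants_passing`,
#'   `gene_aggregates`, `tallies`, `median_vaf`, `per_family` (variant
#'   counts with mean and range over all cohort families),
#'   `zero_variant_families`, `chip_cautions` (final variants in
#'   CHIP-associated genes, whose blood-derived origin cannot be assumed
#'   germline), `synonymous_splicing` (when a `splice_impact` column is
#'   present), and the `config`.
#' @export
run_discovery_pipeline <- function(cohort, variants, genotypes = NULL,
                                   config = discovery_config(),
                                   external_lists = NULL,
                                   sporadic_genes = NULL) {
  stopifnot(inherits(cohort, "fam_cohort"))
  pre <- prefilter_variants(variants, af_max = config$prefilter_af_max,
                            min_depth = config$min_depth)
  seg <- if (!is.null(genotypes)) {
    segregation_table(genotypes, cohort, strict = config$strict_segregation)
  }
  passing <- apply_variant_criteria(pre, seg, config)
  agg <- aggregate_gene_recurrence(passing, config)
  if (!is.null(external_lists)) {
    agg <- rescue_by_cross_reference(agg, passing, external_lists)
  } else {
    agg$rescue_source <- NA_character_
  }
  if (!is.null(sporadic_genes)) {
    agg <- annotate_sporadic_overlap(agg, sporadic_genes)
  }
  included_genes <- agg$gene[agg$included]
  final <- passing[passing$gene %in% included_genes, , drop = FALSE]

  fam_ids <- cohort$families$family_id
  per_family <- final |>
    distinct(.data$family_id, .data$variant_id) |>
    count(.data$family_id, name = "n_variants") |>
    right_join(tibble(family_id = fam_ids), by = "family_id") |>
    mutate(n_variants = ifelse(is.na(.data$n_variants), 0L, .data$n_variants))
  synon <- if ("splice_impact" %in% names(variants)) {
    scan_synonymous_splicing(pre, config$synonymous_splice_threshold)
  }

  report <- structure(list(
    variants_final = final,
    variants_passing = passing,
    gene_aggregates = agg,
    tallies = list(
      input = nrow(as_tibble(variants)),
      prefiltered = nrow(pre),
      passing = nrow(passing),
      final = nrow(final),
      genes_included = length(included_genes),
      prefilter_exclusions = attr(pre, "exclusions"),
      criteria_exclusions = attr(passing, "criteria_exclusions")
    ),
    median_vaf = if (nrow(final)) median(final$vaf, na.rm = TRUE) else NA_real_,
    per_family = per_family,
    mean_variants_per_family = nrow(distinct(final, .data$family_id,
                                             .data$variant_id)) /
      max(length(fam_ids), 1),
    variants_per_family_range = if (nrow(per_family))
      range(per_family$n_variants) else c(NA_integer_, NA_integer_),
    zero_variant_families = per_family$family_id[per_family$n_variants == 0],
    chip_cautions = final[final$gene %in% config$chip_genes, , drop = FALSE],
    synonymous_splicing = synon,
    config = config
  ), class = "fam_discovery")
  attr(report, "sim_id") <- attr(variants, "sim_id", exact = TRUE)
  report
}

#' @export
print.fam_discovery <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(
    "<fam_discovery> %d input -> %d pre-filtered -> %d passing -> %d final variants in %d genes\n",
    t$input, t$prefiltered, t$passing, t$final, t$genes_included))
  cat(sprintf("  median VAF of final list: %.2f; %.1f variants/family (range %d-%d); %d family(ies) with none\n",
              x$median_vaf, x$mean_variants_per_family,
              x$variants_per_family_range[1], x$variants_per_family_range[2],
              length(x$zero_variant_families)))
  if (nrow(x$chip_cautions)) {
    cat(sprintf("  CHIP caution: %d variant(s) in %s\n",
                nrow(x$chip_cautions),
                paste(unique(x$chip_cautions$gene), collapse = ", ")))
  }
  invisible(x)
}

#' Summary statistics of an externally assembled final variant list
#'
#' Computes the headline summaries of a prioritized variant table: the
#' number of variants, genes and distinct families, the median VAF, and the
#' mean variants per family for a given discovery-family denominator.
#'
#' @param path TSV with at least `family_id`, `gene`, `vaf` columns (one
#'   row per prioritized variant).
#' @param n_discovery_families denominator for the per-family mean.
#' @return list of summary statistics.
#' @export
summarize_final_variant_list <- function(path, n_discovery_families = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("family_id", "gene", "vaf") %in% names(tab)))
  n_fam <- n_discovery_families %||% length(unique(tab$family_id))
  list(
    n_variants = nrow(tab),
    n_genes = length(unique(tab$gene)),
    n_families = length(unique(tab$family_id)),
    median_vaf = median(tab$vaf, na.rm = TRUE),
    mean_variants_per_family = nrow(tab) / n_fam
  )
}
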