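# Triage of variants in established MDS/AML predisposition loci.
#
# Families carrying a pathogenic or likely pathogenic variant at a known
# locus form Group 1; molecularly unexplained families proceed to the exome
# discovery cascade (Group 2). Families whose only finding is a variant of
# unknown significance are held out of both ("VUS-hold"): they are neither
# explained nor clean discovery material.

KNOWN_TIERS <- c("high", "moderate", "emerging")
INHERITANCE_MODELS <- c("AD_het", "AR_biallelic", "XL_hemizygous")

#' Load the known predisposition gene configuration
#'
#' The packaged default carries three evidence tiers: nine high-evidence
#' loci (ANKRD26, CEBPA, DDX41, ETV6, GATA2, RUNX1, TERC, TERT, TP53), six
#' with moderate evidence (ACD, CHEK2, RTEL1, SAMD9, SAMD9L, SRP72), and an
#' emerging tier of genes from basic research or other inherited
#' hematological syndromes (ATG2B/GSKIP, ERCC6L2, Fanconi genes, MBD4,
#' MECOM, SBDS, WAS). Variants at these loci are heterozygous except for
#' the biallelic loci (ERCC6L2, FANC genes, SBDS) and hemizygous WAS.
#'
#' @param path TSV with columns `gene`, `tier`
#'   (`high`/`moderate`/`emerging`), `inheritance`
#'   (`AD_het`/`AR_biallelic`/`XL_hemizygous`). Defaults to the packaged
#'   configuration.
#' @return tibble, one row per gene.
#' @export
read_known_genes <- function(path = NULL) {
  path <- path %||% famprio_extdata("known_genes.tsv")
  cfg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!nrow(cfg)) {
    return(tibble(gene = character(), tier = character(),
                  inheritance = character()))
  }
  need <- c("gene", "tier", "inheritance")
  if (!all(need %in% names(cfg))) {
    stop("known-gene config must have columns gene, tier, inheritance",
         call. = FALSE)
  }
  if (anyDuplicated(cfg$gene)) {
    stop("duplicate gene in known-gene config: ",
         cfg$gene[duplicated(cfg$gene)][1], call. = FALSE)
  }
  bad <- setdiff(cfg$tier, KNOWN_TIERS)
  if (length(bad)) stop("unknown tier: ", bad[1], call. = FALSE)
  bad <- setdiff(cfg$inheritance, INHERITANCE_MODELS)
  if (length(bad)) stop("unknown inheritance model: ", bad[1], call. = FALSE)
  as_tibble(cfg[need])
}

#' Assess a variant in an established predisposition gene
#'
#' Applies the targeted-sequencing pathogenicity rule: a variant previously
#' described in familial MDS/AML is pathogenic outright; a new variant is
#' likely pathogenic when it satisfies all of (1) minor allele frequency
#' `< 1e-5` in ExAC and gnomAD (or absent), (2) VAF `> 0.30`,
#' (3) 2-of-4 predictor consensus, (4) no ACMG benign assertion (a
#' curator-supplied judgement, since ACMG classification draws on evidence
#' outside this package), and (5) segregation not refuted where testing was
#' possible. Partial evidence yields a VUS; a curator "uncertain" ACMG
#' judgement caps the category at VUS; an ACMG benign assertion or refuted
#' segregation excludes the variant.
#'
#' Zygosity is checked against the gene's inheritance model: autosomal
#' dominant heterozygous loci with VAF > 0.7 are flagged as a possible
#' loss-of-heterozygosity anomaly (category unchanged); autosomal recessive
#' loci require two variants in the gene in the same individual (compound
#' heterozygote, trans phase unverified) or a homozygous-range VAF; X-linked
#' loci expect hemizygous-range VAF (~1) in males.
#'
#' @param variant one-row tibble (or list) with the annotated-variant
#'   fields (`gene`, `vaf`, `exac_af`, `gnomad_af`, `consequence`,
#'   `splice_offset`, predictor columns).
#' @param gene_cfg the matching row of [read_known_genes()].
#' @param seg optional `segregation_result` (or its `status` string).
#' @param known_db established-variant lookup table (tibble with `gene`,
#'   `hgvs_c`, `hgvs_p`); defaults to the packaged set.
#' @param acmg curator ACMG judgement: `"not_benign"` (default),
#'   `"uncertain"`, or `"benign"`.
#' @param sex carrier sex, used for X-linked zygosity.
#' @param n_gene_variants number of distinct variants this carrier holds in
#'   the gene (for the biallelic check); default 1.
#' @return a `pathogenicity_call`: list with `category`
#'   (`pathogenic`/`likely_pathogenic`/`VUS`/`excluded`), named logical
#'   `evidence` flags, and `notes`.
#' @export
assess_known_variant <- function(variant, gene_cfg, seg = NULL,
                                 known_db = NULL,
                                 acmg = c("not_benign", "uncertain", "benign"),
                                 sex = NULL, n_gene_variants = 1) {
  acmg <- match.arg(acmg)
  v <- as.list(variant)
  if (is.null(gene_cfg) || !nrow(as_tibble(gene_cfg))) {
    stop(sprintf(
      "gene %s is not an established predisposition locus; route it through the discovery cascade",
      v$gene %||% "?"), call. = FALSE)
  }
  gene_cfg <- as.list(as_tibble(gene_cfg)[1, ])
  if (!is.null(v$gene) && !is.na(v$gene) && v$gene != gene_cfg$gene) {
    stop("variant gene does not match the supplied gene config", call. = FALSE)
  }
  known_db <- known_db %||% known_variant_db()
  seg_status <- if (is.null(seg)) "untestable"
  else if (inherits(seg, "segregation_result")) seg$status else as.character(seg)

  notes <- character()
  db <- known_db[known_db$gene == gene_cfg$gene, , drop = FALSE]
  hc <- v$hgvs_c %||% NA_character_
  hp <- v$hgvs_p %||% NA_character_
  prev <- (!is.na(hc) && any(!is.na(db$hgvs_c) & db$hgvs_c == hc)) ||
    (!is.na(hp) && any(!is.na(db$hgvs_p) & db$hgvs_p == hp))

  vaf <- v$vaf %||% NA_real_
  maf_ok <- (is.na(v$exac_af %||% NA) | (v$exac_af %||% NA) < 1e-5) &&
    (is.na(v$gnomad_af %||% NA) | (v$gnomad_af %||% NA) < 1e-5)
  vaf_ok <- is.na(vaf) || vaf > 0.30
  pred_ok <- predictor_consensus(
    tibble(polyphen2 = v$polyphen2 %||% "missing",
           mutation_taster = v$mutation_taster %||% "missing",
           sift = v$sift %||% "missing",
           provean = v$provean %||% "missing"),
    v$consequence %||% "other", v$splice_offset %||% NA)
  seg_ok <- seg_status != "refuted"

  zyg_ok <- TRUE
  if (gene_cfg$inheritance == "AD_het") {
    if (!is.na(vaf) && vaf > 0.7) {
      notes <- c(notes, "zygosity anomaly: VAF in homozygous range under an AD_het model (possible LOH)")
    }
  } else if (gene_cfg$inheritance == "AR_biallelic") {
    hom <- !is.na(vaf) && vaf > 0.7
    if (n_gene_variants >= 2) {
      notes <- c(notes, "compound heterozygote assumed biallelic (trans phase unverified)")
    } else if (!hom) {
      zyg_ok <- FALSE
      notes <- c(notes, "single heterozygous variant at a biallelic locus")
    }
  } else if (gene_cfg$inheritance == "XL_hemizygous") {
    if (identical(sex, "male")) {
      zyg_ok <- is.na(vaf) || vaf > 0.8
      if (!zyg_ok) notes <- c(notes, "male carrier without hemizygous-range VAF at an X-linked locus")
    }
  }

  evidence <- c(
    previously_described = prev,
    maf_lt_1e5 = isTRUE(maf_ok),
    vaf_gt_30 = isTRUE(vaf_ok),
    predictors_2of4 = isTRUE(pred_ok),
    acmg_not_benign = acmg != "benign",
    segregation_supported = seg_ok,
    zygosity_consistent = zyg_ok
  )

  category <- if (acmg == "benign" || seg_status == "refuted") {
    "excluded"
  } else if (prev) {
    "pathogenic"
  } else if (all(evidence[c("maf_lt_1e5", "vaf_gt_30", "predictors_2of4",
                            "acmg_not_benign", "segregation_supported",
                            "zygosity_consistent")]) &&
             acmg != "uncertain") {
    "likely_pathogenic"
  } else {
    "VUS"
  }
  structure(list(category = category, evidence = evidence, notes = notes),
            class = "pathogenicity_call")
}

#' @export
print.pathogenicity_call <- function(x, ...) {
  cat(sprintf("<pathogenicity_call> %s\n", x$category))
  cat("  evidence:", paste(names(x$evidence)[x$evidence], collapse = ", "),
      "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Assign a family to Group 1, Group 2 or VUS-hold
#'
#' A family with at least one pathogenic or likely pathogenic call at an
#' established locus is Group 1 (molecularly explained). A family with no
#' calls proceeds to discovery (Group 2). A family whose best finding is a
#' VUS is held out of both: it is not explained, but including it in the
#' discovery denominator would contaminate gene discovery with families
#' that may already carry their causal lesion.
#'
#' @param calls character vector of call categories, a list of
#'   `pathogenicity_call` objects, or a tibble with a `category` column.
#'   Empty input means no known-locus findings.
#' @return `"group1"`, `"group2"`, or `"vus_hold"`.
#' @export
assign_family_group <- function(calls) {
  cats <- if (is.data.frame(calls)) {
    calls$category
  } else if (is.list(calls) && length(calls) &&
             inherits(calls[[1]], "pathogenicity_call")) {
    vapply(calls, function(x) x$category, character(1))
  } else {
    as.character(calls)
  }
  cats <- cats[!is.na(cats) & cats != "none"]
  if (any(cats %in% c("pathogenic", "likely_pathogenic"))) return("group1")
  if (any(cats == "VUS")) return("vus_hold")
  "group2"
}

#' Group assignment for a whole cohort of per-family calls
#'
#' @param family_calls tibble with `family_id` and `category` (one row per
#'   known-locus call; families with `category == "none"` or absent rows
#'   have no findings).
#' @return tibble with `family_id` and `group`, plus attribute `"counts"`
#'   (named vector over group1/group2/vus_hold with percentages of the
#'   cohort).
#' @export
assign_family_groups <- function(family_calls) {
  fc <- as_tibble(family_calls)
  out <- fc |>
    group_by(.data$family_id) |>
    summarise(group = assign_family_group(.data$category), .groups = "drop")
  n <- nrow(out)
  counts <- table(factor(out$group, c("group1", "group2", "vus_hold")))
  attr(out, "counts") <- tibble(
    group = names(counts),
    n_families = as.integer(counts),
    pct = round(100 * as.integer(counts) / n)
  )
  out
}
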