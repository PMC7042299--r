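# Pedigree + phenotype handling for familial MDS/AML cohorts.
#
# A cohort is stored as a single members table (one row per individual) plus a
# derived per-family table. Affection follows the PLINK convention
# (2 = affected, 1 = unaffected, 0/-9 = unknown); diagnoses use a controlled
# vocabulary so that family phenotype categories are reproducible.

#' @rdname read_pedigree
#' @export
DIAGNOSIS_LEVELS <- c("MDS", "AML", "thrombocytopenia",
                      "BMF/aplastic_anemia", "other_heme", "none")

#' @rdname classify_family_phenotype
#' @export
PHENOTYPE_CATEGORIES <- c("MDS", "AML", "MDS/AML", "MDS/AML/TCP", "MDS/AML/BMF")

normalize_diagnosis <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(
    "mds" = "MDS",
    "aml" = "AML",
    "tcp" = "thrombocytopenia",
    "thrombocytopenia" = "thrombocytopenia",
    "bmf" = "BMF/aplastic_anemia",
    "aplastic_anemia" = "BMF/aplastic_anemia",
    "aplastic anemia" = "BMF/aplastic_anemia",
    "bmf/aplastic_anemia" = "BMF/aplastic_anemia",
    "other_heme" = "other_heme",
    "other" = "other_heme",
    "none" = "none"
  )
  out <- unname(map[key])
  out[is.na(key) | key == ""] <- NA_character_
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    stop("unrecognized diagnosis value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a pedigree (PED/FAM) file with an optional phenotype table
#'
#' Parses a PLINK-style 6-column pedigree file (`FID IID PAT MAT SEX PHENO`,
#' whitespace separated, `0` = missing parent) and joins per-individual
#' clinical phenotype information. The phenotype table is a TSV keyed by
#' `family_id` and `individual_id` with optional columns `diagnosis`
#' (`r paste(DIAGNOSIS_LEVELS, collapse = ", ")`), `age_at_onset`,
#' `index_case` (logical; the explicitly flagged index case of the family)
#' and `sampled` (logical; genotype material available).
#'
#' Affection status is mapped `2 -> affected`, `1 -> unaffected`,
#' `0`/`-9 -> unknown`. Parent identifiers must refer to members of the same
#' family and the parent graph must be acyclic; the index case must be an
#' affected member. Families whose sampled affected members number fewer than
#' two are flagged `index_only`: segregation in such families is untestable,
#' which downstream stages treat as "retained, untested" rather than as
#' evidence against a variant.
#'
#' @param ped_path path to the 6-column pedigree file.
#' @param phenotype_path optional path to the phenotype TSV.
#' @return A `fam_cohort` object: a list with `members` (tibble, one row per
#'   individual) and `families` (tibble with `family_id`, `index_case_id`,
#'   `n_members`, `n_affected`, `n_unaffected`, `index_only`).
#' @examples
#' ped <- tempfile(fileext = ".fam")
#' writeLines(c("F1 P1 0 0 1 2", "F1 M1 0 0 2 1", "F1 C1 P1 M1 1 1"), ped)
#' cohort <- read_pedigree(ped)
#' cohort$families
#' @export
read_pedigree <- function(ped_path, phenotype_path = NULL) {
  if (!file.exists(ped_path)) {
    stop("pedigree file not found: ", ped_path, call. = FALSE)
  }
  lines <- readLines(ped_path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    i <- which(nf != 6L)[1]
    stop(sprintf("malformed pedigree line %d: expected 6 columns, found %d",
                 lineno[i], nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  members <- tibble(
    family_id = m[, 1],
    individual_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(c("1" = "male", "2" = "female")[m[, 5]]) %|na|% "unknown",
    affection = dplyr::case_when(
      m[, 6] == "2" ~ "affected",
      m[, 6] == "1" ~ "unaffected",
      TRUE ~ "unknown"
    ),
    diagnosis = NA_character_,
    age_at_onset = NA_real_,
    index_case = FALSE,
    sampled = TRUE
  )
  if (anyDuplicated(members[c("family_id", "individual_id")])) {
    stop("duplicated individual id within a family", call. = FALSE)
  }

  if (!is.null(phenotype_path)) {
    pheno <- readr::read_tsv(phenotype_path, show_col_types = FALSE,
                             progress = FALSE)
    need <- c("family_id", "individual_id")
    if (!all(need %in% names(pheno))) {
      stop("phenotype table must contain family_id and individual_id columns",
           call. = FALSE)
    }
    pheno$family_id <- as.character(pheno$family_id)
    pheno$individual_id <- as.character(pheno$individual_id)
    orphan <- anti_join(pheno, members, by = need)
    if (nrow(orphan)) {
      stop("phenotype rows for unknown individuals: ",
           paste(orphan$individual_id, collapse = ", "), call. = FALSE)
    }
    if ("diagnosis" %in% names(pheno)) {
      pheno$diagnosis <- normalize_diagnosis(pheno$diagnosis)
    }
    keep_cols <- intersect(
      c("family_id", "individual_id", "diagnosis", "age_at_onset",
        "index_case", "sampled"), names(pheno))
    pheno <- pheno[keep_cols]
    if ("index_case" %in% names(pheno)) {
      pheno$index_case <- isTRUE_vec(pheno$index_case)
    }
    if ("sampled" %in% names(pheno)) {
      pheno$sampled <- is.na(pheno$sampled) | isTRUE_vec(pheno$sampled)
    }
    if ("age_at_onset" %in% names(pheno)) {
      pheno$age_at_onset <- as.numeric(pheno$age_at_onset)
    }
    members <- rows_update(members, pheno, by = need, unmatched = "ignore")
  }
  # default index case: first affected member of the family
  members <- members |>
    group_by(.data$family_id) |>
    mutate(index_case = if (any(.data$index_case)) .data$index_case else
      seq_along(.data$index_case) == match("affected", .data$affection)) |>
    ungroup()

  new_cohort(members)
}

`%|na|%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == 1 | x == "TRUE")

#' Construct a cohort object from a members table
#'
#' Validates pedigree structure (parent references, acyclicity, index case
#' affected) and derives the per-family summary table.
#'
#' @param members tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affection`, `diagnosis`,
#'   `age_at_onset`, `index_case`, `sampled`.
#' @return a `fam_cohort` object.
#' @export
new_cohort <- function(members) {
  members <- as_tibble(members)
  for (fam in split(members, members$family_id)) {
    fid <- fam$family_id[1]
    ids <- fam$individual_id
    for (col in c("father_id", "mother_id")) {
      bad <- setdiff(stats::na.omit(fam[[col]]), ids)
      if (length(bad)) {
        stop(sprintf("family %s: parent id '%s' does not refer to a member",
                     fid, bad[1]), call. = FALSE)
      }
    }
    # acyclicity: iteratively peel individuals whose parents are all resolved
    remaining <- ids
    repeat {
      if (!length(remaining)) break
      par <- fam[match(remaining, fam$individual_id), c("father_id", "mother_id")]
      founder <- !(par$father_id %in% remaining) & !(par$mother_id %in% remaining)
      if (!any(founder)) {
        stop(sprintf("family %s: pedigree contains a cycle", fid),
             call. = FALSE)
      }
      remaining <- remaining[!founder]
    }
    if (!any(fam$affection == "affected")) {
      stop(sprintf("family %s has no affected member", fid), call. = FALSE)
    }
    idx <- fam$individual_id[fam$index_case]
    if (length(idx) && any(fam$affection[fam$index_case] != "affected")) {
      stop(sprintf("family %s: index case must be affected", fid),
           call. = FALSE)
    }
  }
  families <- members |>
    group_by(.data$family_id) |>
    summarise(
      index_case_id = .data$individual_id[.data$index_case][1],
      n_members = n(),
      n_affected = sum(.data$affection == "affected"),
      n_unaffected = sum(.data$affection == "unaffected"),
      index_only = sum(.data$affection == "affected" & .data$sampled) < 2,
      .groups = "drop"
    )
  structure(list(members = members, families = families),
            class = "fam_cohort")
}

#' @export
print.fam_cohort <- function(x, ...) {
  cat(sprintf(
    "<fam_cohort> %d families, %d individuals (%d affected, %d unaffected)\n",
    nrow(x$families), nrow(x$members),
    sum(x$members$affection == "affected"),
    sum(x$members$affection == "unaffected")))
  invisible(x)
}

#' Classify the clinical phenotype category of a family
#'
#' The category is determined by the set of diagnoses among affected members.
#' Every family must contain at least one member diagnosed with MDS or AML
#' (the cohort inclusion rule); the mutually exclusive categories are then
#' resolved by precedence: any bone-marrow-failure/aplastic-anemia member
#' gives `MDS/AML/BMF`; otherwise any thrombocytopenia member gives
#' `MDS/AML/TCP`; otherwise co-occurrence of MDS and AML gives `MDS/AML`;
#' otherwise the single myeloid diagnosis (`MDS` or `AML`).
#'
#' @param x a `fam_cohort`, or a members tibble for a single family.
#' @param family family id when `x` is a cohort with several families.
#' @return a single category string (see `PHENOTYPE_CATEGORIES`).
#' @export
classify_family_phenotype <- function(x, family = NULL) {
  members <- if (inherits(x, "fam_cohort")) x$members else as_tibble(x)
  if (!is.null(family)) members <- members[members$family_id == family, ]
  if (length(unique(members$family_id)) != 1) {
    stop("supply a single family (use the `family` argument)", call. = FALSE)
  }
  d <- members$diagnosis[members$affection == "affected"]
  d <- d[!is.na(d) & d != "none"]
  has_mds <- "MDS" %in% d
  has_aml <- "AML" %in% d
  if (!has_mds && !has_aml) {
    stop(sprintf(
      "family %s has no member diagnosed with MDS or AML (cohort inclusion rule)",
      members$family_id[1]), call. = FALSE)
  }
  if ("BMF/aplastic_anemia" %in% d) return("MDS/AML/BMF")
  if ("thrombocytopenia" %in% d) return("MDS/AML/TCP")
  if (has_mds && has_aml) return("MDS/AML")
  if (has_mds) "MDS" else "AML"
}

#' Phenotype category of every family in a cohort
#'
#' @param cohort a `fam_cohort`.
#' @return tibble with `family_id` and `category`.
#' @export
family_phenotypes <- function(cohort) {
  stopifnot(inherits(cohort, "fam_cohort"))
  fams <- split(cohort$members, cohort$members$family_id)
  tibble(
    family_id = names(fams),
    category = vapply(fams, classify_family_phenotype, character(1))
  )
}

#' Summarize a familial MDS/AML cohort
#'
#' Counts and percentages of families per clinical phenotype category, plus
#' consanguinity if a logical `consanguineous` column is present in the
#' members table. Percentages are reported to one decimal place of
#' `100 * count / n_families`; phenotype counts partition the cohort.
#'
#' @param cohort a `fam_cohort`.
#' @return tibble with `characteristic`, `n_families`, `pct`; cohort totals
#'   are attached as attribute `"totals"`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "fam_cohort"))
  if (!nrow(cohort$families)) stop("empty cohort", call. = FALSE)
  n_fam <- nrow(cohort$families)
  cats <- family_phenotypes(cohort)
  counts <- table(factor(cats$category, levels = PHENOTYPE_CATEGORIES))
  out <- tibble(
    characteristic = PHENOTYPE_CATEGORIES,
    n_families = as.integer(counts),
    pct = round(100 * as.integer(counts) / n_fam, 1)
  )
  if ("consanguineous" %in% names(cohort$members)) {
    consang <- cohort$members |>
      group_by(.data$family_id) |>
      summarise(flag = any(isTRUE_vec(.data$consanguineous)),
                .groups = "drop")
    out <- bind_rows(out, tibble(
      characteristic = "Consanguinity",
      n_families = sum(consang$flag),
      pct = round(100 * sum(consang$flag) / n_fam, 1)
    ))
  }
  attr(out, "totals") <- list(
    n_families = n_fam,
    n_individuals = nrow(cohort$members),
    n_affected = sum(cohort$members$affection == "affected"),
    n_unaffected = sum(cohort$members$affection == "unaffected")
  )
  out
}

#' Write a cohort back to PED + phenotype TSV
#'
#' Inverse of [read_pedigree()]; writing then re-reading reproduces the
#' cohort field for field.
#'
#' @param cohort a `fam_cohort`.
#' @param ped_path,phenotype_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, ped_path, phenotype_path) {
  stopifnot(inherits(cohort, "fam_cohort"))
  m <- cohort$members
  ped <- data.frame(
    fid = m$family_id,
    iid = m$individual_id,
    pat = ifelse(is.na(m$father_id), "0", m$father_id),
    mat = ifelse(is.na(m$mother_id), "0", m$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[m$sex],
    pheno = c(affected = "2", unaffected = "1", unknown = "0")[m$affection]
  )
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  pheno <- m[c("family_id", "individual_id", "diagnosis", "age_at_onset",
               "index_case", "sampled")]
  readr::write_tsv(pheno, phenotype_path, na = "")
  invisible(c(ped_path, phenotype_path))
}
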