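# Pedigree segregation assessment tolerant of reduced penetrance.
#
# Reduced penetrance and late onset are features of established familial
# MDS/AML loci (GATA2, DDX41, C-terminal CEBPA), so an unaffected carrier is
# recorded but never counted against a variant by default. Only a genotyped
# AFFECTED non-carrier refutes; with fewer than two genotyped affected
# members the question is untestable and the variant is retained.

#' Assess segregation of a variant within one family
#'
#' @param calls tibble with `individual_id`, `status`
#'   (`carrier`/`non_carrier`/`not_genotyped`) and optional `vaf`. Members
#'   absent from `calls` are treated as not genotyped.
#' @param members members tibble of a single family (or a `fam_cohort`
#'   subset), carrying `individual_id` and `affection`.
#' @param strict when `TRUE`, an unaffected carrier refutes segregation
#'   (fully penetrant model). Off by default.
#' @return a `segregation_result`: list with `status`
#'   (`segregates`/`refuted`/`untestable`), `n_affected_carriers`,
#'   `n_affected_tested`, `unaffected_carriers`, `supporting_noncarriers`
#'   (healthy genotyped non-carriers, reported as supporting context only).
#'
#' @details
#' * `refuted`: at least one genotyped affected member does not carry the
#'   variant.
#' * `segregates`: at least two affected members were genotyped and all of
#'   them carry the variant.
#' * `untestable`: fewer than two affected members genotyped (e.g. families
#'   with material on the index case only).
#' @export
assess_segregation <- function(calls, members, strict = FALSE) {
  if (inherits(members, "fam_cohort")) members <- members$members
  members <- as_tibble(members)
  calls <- as_tibble(calls)
  unknown <- setdiff(calls$individual_id, members$individual_id)
  if (length(unknown)) {
    stop("genotype call for unknown individual id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  status <- calls$status[match(members$individual_id, calls$individual_id)]
  status[is.na(status)] <- "not_genotyped"
  affected <- members$affection == "affected"
  unaffected <- members$affection == "unaffected"
  tested <- status != "not_genotyped"

  n_aff_tested <- sum(affected & tested)
  n_aff_carrier <- sum(affected & status == "carrier")
  unaff_carriers <- members$individual_id[unaffected & status == "carrier"]
  support_noncarr <- members$individual_id[unaffected & status == "non_carrier"]

  refuted <- any(affected & status == "non_carrier")
  if (strict && length(unaff_carriers)) refuted <- TRUE
  out_status <- if (refuted) {
    "refuted"
  } else if (n_aff_tested >= 2 && n_aff_carrier == n_aff_tested) {
    "segregates"
  } else {
    "untestable"
  }
  structure(list(
    status = out_status,
    n_affected_carriers = n_aff_carrier,
    n_affected_tested = n_aff_tested,
    unaffected_carriers = unaff_carriers,
    supporting_noncarriers = support_noncarr
  ), class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation> %s (%d/%d affected carriers tested)\n",
              x$status, x$n_affected_carriers, x$n_affected_tested))
  if (length(x$unaffected_carriers)) {
    cat("  unaffected carriers:",
        paste(x$unaffected_carriers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Segregation status for every (variant, family) pair
#'
#' Vectorized counterpart of [assess_segregation()] operating on a long
#' genotype table; used by the discovery pipeline.
#'
#' @param genotypes tibble with `variant_id`, `family_id`, `individual_id`,
#'   `carrier` (1 = carrier, 0 = genotyped non-carrier, `NA` = not
#'   genotyped).
#' @param cohort a `fam_cohort` supplying affection status.
#' @param strict see [assess_segregation()].
#' @return tibble with `variant_id`, `family_id`, `status`,
#'   `n_affected_tested`, `n_affected_carriers`, `n_unaffected_carriers`.
#' @export
segregation_table <- function(genotypes, cohort, strict = FALSE) {
  stopifnot(inherits(cohort, "fam_cohort"))
  g <- as_tibble(genotypes) |>
    left_join(cohort$members[c("family_id", "individual_id", "affection")],
              by = c("family_id", "individual_id"))
  if (anyNA(g$affection)) {
    stop("genotype rows refer to individuals absent from the cohort",
         call. = FALSE)
  }
  g |>
    group_by(.data$variant_id, .data$family_id) |>
    summarise(
      n_affected_tested = sum(.data$affection == "affected" &
                                !is.na(.data$carrier)),
      n_affected_carriers = sum(.data$affection == "affected" &
                                  !is.na(.data$carrier) & .data$carrier == 1),
      n_affected_noncarriers = sum(.data$affection == "affected" &
                                     !is.na(.data$carrier) & .data$carrier == 0),
      n_unaffected_carriers = sum(.data$affection == "unaffected" &
                                    !is.na(.data$carrier) & .data$carrier == 1),
      .groups = "drop"
    ) |>
    mutate(
      status = dplyr::case_when(
        .data$n_affected_noncarriers > 0 ~ "refuted",
        strict & .data$n_unaffected_carriers > 0 ~ "refuted",
        .data$n_affected_tested >= 2 &
          .data$n_affected_carriers == .data$n_affected_tested ~ "segregates",
        TRUE ~ "untestable"
      )
    ) |>
    select("variant_id", "family_id", "status", "n_affected_tested",
           "n_affected_carriers", "n_unaffected_carriers")
}
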