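# Telomere length estimation from monochrome multiplex qPCR.
#
# The amount of telomeric DNA (T) and of a single-copy gene (S) are read
# off per-channel standard curves fitted to a dilution series; their ratio
# T/S is proportional to mean telomere length and is compared with the
# empirical distribution of healthy-control ratios. Samples run in
# quadruplicate; per-replicate quantities (not Cq values) are averaged,
# since quantity is the additive scale.

#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq = slope * log10(quantity) + intercept`. The
#' amplification efficiency is derived as `10^(-1/slope) - 1` (1.0 for
#' perfect doubling per cycle).
#'
#' @param points data frame with `log10_quantity` and `cq` (>= 3 distinct
#'   dilution points).
#' @return a `standard_curve`: list with `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n_points`.
#' @examples
#' d <- data.frame(log10_quantity = 0:3, cq = 30 - (0:3) / log10(2))
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(points) {
  p <- as.data.frame(points)
  stopifnot(all(c("log10_quantity", "cq") %in% names(p)))
  p <- p[stats::complete.cases(p[c("log10_quantity", "cq")]), ]
  if (length(unique(p$log10_quantity)) < 3) {
    stop("standard curve needs >= 3 distinct dilution points", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10_quantity, data = p)
  fit_summary <- suppressWarnings(summary(fit))  # exact fits are legitimate
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("invalid amplification: standard-curve slope must be negative (got ",
         signif(slope, 3), ")", call. = FALSE)
  }
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = fit_summary$r.squared,
    efficiency = 10^(-1 / slope) - 1,
    n_points = nrow(p)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

cq_to_quantity <- function(cq, curve) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Telomere / single-copy-gene (T/S) ratio from replicate Cq values
#'
#' Per-replicate quantities are interpolated from the channel's standard
#' curve (`10^((Cq - intercept)/slope)`) and averaged; the result is the
#' ratio of mean T quantity to mean S quantity.
#'
#' @param t_cq,s_cq replicate Cq values for the telomere and single-copy
#'   channels (typically quadruplicate).
#' @param t_curve,s_curve per-channel [fit_standard_curve()] results.
#' @param sample_id sample label.
#' @param cq_tolerance maximum within-channel Cq spread before a replicate
#'   dispersion warning flag is raised (default 0.5 cycles).
#' @return a `telomere_result`: list with `sample_id`, `t_quantity`,
#'   `s_quantity`, `ts_ratio`, `replicate_warning`, and (until controls are
#'   supplied) `percentile_vs_controls = NA`, `short_flag = NA`.
#' @export
compute_ts_ratio <- function(t_cq, s_cq, t_curve, s_curve,
                             sample_id = NA_character_, cq_tolerance = 0.5) {
  stopifnot(inherits(t_curve, "standard_curve"),
            inherits(s_curve, "standard_curve"))
  t_cq <- t_cq[!is.na(t_cq)]; s_cq <- s_cq[!is.na(s_cq)]
  if (!length(t_cq) || !length(s_cq)) {
    stop("need at least one replicate Cq per channel", call. = FALSE)
  }
  spread <- max(diff(range(t_cq)), diff(range(s_cq)))
  warn <- spread > cq_tolerance
  if (warn) {
    warning(sprintf("replicate Cq spread %.2f exceeds tolerance %.2f",
                    spread, cq_tolerance), call. = FALSE)
  }
  tq <- mean(cq_to_quantity(t_cq, t_curve))
  sq <- mean(cq_to_quantity(s_cq, s_curve))
  structure(list(
    sample_id = sample_id,
    t_quantity = tq,
    s_quantity = sq,
    ts_ratio = tq / sq,
    replicate_warning = warn,
    percentile_vs_controls = NA_real_,
    short_flag = NA
  ), class = "telomere_result")
}

#' @export
print.telomere_result <- function(x, ...) {
  cat(sprintf("<telomere_result> %s T/S = %.3f", x$sample_id, x$ts_ratio))
  if (!is.na(x$short_flag)) {
    cat(sprintf(" (percentile %.1f, short: %s)", x$percentile_vs_controls,
                x$short_flag))
  }
  cat("\n")
  invisible(x)
}

#' Flag a short telomere against healthy-control T/S ratios
#'
#' Rank-based, distribution-free comparison: the reported percentile is the
#' proportion of controls with a strictly smaller ratio, and the short flag
#' is raised when the sample ratio falls strictly below the empirical
#' `centile`-th percentile of the controls (type-1/inverse-ECDF quantile, an
#' observed control value; a ratio exactly equal to it is not flagged).
#'
#' @param result a `telomere_result` (or a bare numeric ratio).
#' @param controls numeric vector of control T/S ratios.
#' @param centile flagging centile (default 10).
#' @param min_controls minimum usable control-set size (default 20); with
#'   fewer controls the flag is left `NA` with a warning.
#' @return the `telomere_result` with `percentile_vs_controls` and
#'   `short_flag` filled in.
#' @export
flag_short_telomere <- function(result, controls, centile = 10,
                                min_controls = 20) {
  if (is.numeric(result)) {
    result <- structure(list(sample_id = NA_character_, t_quantity = NA_real_,
                             s_quantity = NA_real_, ts_ratio = result,
                             replicate_warning = FALSE,
                             percentile_vs_controls = NA_real_,
                             short_flag = NA),
                        class = "telomere_result")
  }
  stopifnot(inherits(result, "telomere_result"))
  controls <- controls[!is.na(controls)]
  if (length(controls) < min_controls) {
    warning(sprintf("only %d control(s); need >= %d for a centile flag",
                    length(controls), min_controls), call. = FALSE)
    result$percentile_vs_controls <- NA_real_
    result$short_flag <- NA
    return(result)
  }
  r <- result$ts_ratio
  result$percentile_vs_controls <- 100 * mean(controls < r)
  threshold <- unname(quantile(controls, centile / 100, type = 1))
  result$short_flag <- r < threshold
  result
}

#' Read a plate Cq table
#'
#' @param path CSV with columns `sample`, `channel` (`T` or `S`),
#'   `replicate`, `cq`.
#' @return tibble.
#' @export
read_cq_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample", "channel", "cq") %in% names(tab)))
  if (!all(tab$channel %in% c("T", "S"))) {
    stop("channel must be 'T' or 'S'", call. = FALSE)
  }
  as_tibble(tab)
}
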