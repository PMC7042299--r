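# Interval algebra over constitutional deletions.
#
# Coordinates are stored 1-based inclusive so that printed breakpoints
# (e.g. array-CGH deletion calls) are reproduced bit-exactly; BED I/O
# converts to and from the 0-based half-open convention via rtracklayer.

#' A 1-based inclusive genomic interval
#'
#' @param chrom chromosome name (non-empty).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param label optional label (e.g. family id).
#' @return a `genomic_interval` object.
#' @examples
#' genomic_interval("chr21", 36349450, 36572837, "FML029")
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  stopifnot(length(chrom) == 1, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("invalid interval: require start <= end", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 label = as.character(label)),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%.0f-%.0f%s (%s bp)\n", x$chrom, x$start, x$end,
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

as_interval_list <- function(x) {
  if (inherits(x, "genomic_interval")) return(list(x))
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) {
      genomic_interval(x$chrom[i], x$start[i], x$end[i],
                       if ("label" %in% names(x)) x$label[i] else NA)
    }))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "genomic_interval"))) {
    return(x)
  }
  stop("expected genomic_interval objects or a chrom/start/end data frame",
       call. = FALSE)
}

#' Intersect genomic intervals
#'
#' The maximal interval common to all inputs: `[max(starts), min(ends)]`,
#' or `NULL` when the inputs share no base. Used to delineate the common
#' deleted segment ("hotspot") across independent constitutional deletions,
#' e.g. the segment shared by the three familial RUNX1 deletions.
#'
#' @param intervals a list of [genomic_interval()] objects or a data frame
#'   with `chrom`, `start`, `end` (1-based inclusive). All on one
#'   chromosome.
#' @return a `genomic_interval`, or `NULL` for an empty intersection.
#' @examples
#' intersect_intervals(runx1_deletions())
#' @export
intersect_intervals <- function(intervals) {
  ivs <- as_interval_list(intervals)
  if (!length(ivs)) stop("no intervals supplied", call. = FALSE)
  chroms <- unique(vapply(ivs, `[[`, character(1), "chrom"))
  if (length(chroms) > 1) {
    stop("intervals span several chromosomes: ",
         paste(chroms, collapse = ", "), call. = FALSE)
  }
  s <- max(vapply(ivs, `[[`, numeric(1), "start"))
  e <- min(vapply(ivs, `[[`, numeric(1), "end"))
  if (s > e) return(NULL)
  genomic_interval(chroms, s, e, label = "intersection")
}

#' Length of a genomic interval
#'
#' @param i a [genomic_interval()].
#' @param unit `"bp"` (exact, `end - start + 1`) or `"kb"` (rounded to the
#'   nearest integer, the style used for printed deletion sizes).
#' @examples
#' interval_length(genomic_interval("chr21", 36389457, 37055677), "kb")
#' @export
interval_length <- function(i, unit = c("bp", "kb")) {
  unit <- match.arg(unit)
  bp <- i$end - i$start + 1
  if (unit == "bp") bp else round(bp / 1000)
}

#' Gene features fully covered by an interval
#'
#' @param i a [genomic_interval()].
#' @param features data frame with `chrom`, `start`, `end`, `name`
#'   (1-based inclusive), e.g. a promoter/exon model.
#' @return character vector of the names of features fully contained in
#'   `i`, in genomic order.
#' @export
annotate_interval_features <- function(i, features) {
  f <- as_tibble(features)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(f)))
  hit <- f$chrom == i$chrom & f$start >= i$start & f$end <= i$end
  f <- f[hit, , drop = FALSE]
  f$name[order(f$start)]
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file (0-based half-open on disk).
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write 1-based inclusive intervals as BED
#'
#' @param intervals data frame with `chrom`, `start`, `end` and optional
#'   `name`/`label`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  iv <- as_tibble(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start, end = iv$end)
  )
  nm <- iv[["name"]] %||% iv[["label"]]
  if (!is.null(nm)) gr$name <- nm
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
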