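#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)` coordinates with strand one of `"+"`, `"-"` or `"."`.
#' All interval-consuming functions in the package validate their input
#' through this constructor.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors, `0 <= start < end`.
#' @param name feature names (recycled; default `"."`).
#' @param score numeric scores (recycled; default 0; `NA` allowed).
#' @param strand strand characters in `+ - .` (recycled; default `"."`).
#' @return a data.frame with columns `chrom, start, end, name, score,
#'   strand`, sorted by `(chrom, start, end)`.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
}

#' Validate and sort an interval data frame
#'
#' @param df data.frame with at least `chrom, start, end`; missing
#'   `name/score/strand` columns are filled with defaults.
#' @param what label used in error messages.
#' @return the validated data.frame, sorted by `(chrom, start, end)`.
#' @export
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(df)) {
      stop(sprintf("%s set lacks required column '%s'", what, col))
    }
  }
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  if (nrow(df) == 0) {
    return(df[, c("chrom", "start", "end", "name", "score", "strand"),
              drop = FALSE])
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid %s coordinates (need 0 <= start < end) at row %d: %s:%s-%s",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' at %s row %d (must be one of + - .)",
                 df$strand[bad[1]], what, bad[1]))
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# interval midpoints, floored to an integer base offset
interval_midpoints <- function(df) floor((df$start + df$end) / 2)

# IRanges view of a 0-based half-open interval frame (1-based closed inside)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Count overlaps between point positions and intervals, per chromosome
#'
#' @param chrom,pos0 vectors describing points (0-based positions).
#' @param intervals interval data.frame.
#' @return for each point, TRUE if it falls inside any interval
#'   (half-open semantics).
#' @keywords internal
points_in_intervals <- function(chrom, pos0, intervals) {
  hit <- logical(length(chrom))
  if (nrow(intervals) == 0 || length(chrom) == 0) return(hit)
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(start = pos0[idx] + 1L, width = 1L)
    hit[idx] <- IRanges::overlapsAny(q, .as_iranges(iv))
  }
  hit
}

# index of the interval containing each point (midpoint assignment);
# ties broken by longest interval, then smallest start, as row order after
# sorting. Returns NA where no interval contains the point.
point_interval_index <- function(chrom, pos0, intervals) {
  out <- rep(NA_integer_, length(chrom))
  if (nrow(intervals) == 0 || length(chrom) == 0) return(out)
  for (ch in unique(chrom)) {
    rows <- which(intervals$chrom == ch)
    idx <- which(chrom == ch)
    if (!length(rows)) next
    iv <- intervals[rows, , drop = FALSE]
    q <- IRanges::IRanges(start = pos0[idx] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(q, .as_iranges(iv))
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    len <- iv$end[sh] - iv$start[sh]
    ord <- order(qh, -len, iv$start[sh], sh)
    keep <- !duplicated(qh[ord])
    out[idx[qh[ord][keep]]] <- rows[sh[ord][keep]]
  }
  out
}
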