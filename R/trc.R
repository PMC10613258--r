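#' Parameters for TRC calling
#'
#' @param rfd_threshold absolute mean-RFD cutoff a peak must exceed to be
#'   retained (default 0.75, the homogeneous-directionality criterion).
#' @param min_covered_fraction minimum fraction of a peak covered by
#'   non-missing RFD bins (default 0.5); peaks below it get a missing
#'   mean RFD and are excluded.
#' @param strict logical; TRUE (default) requires `|mean RFD| >`
#'   threshold, FALSE allows `>=`.
#' @return a list of class `trc_params`.
#' @export
trc_params <- function(rfd_threshold = 0.75, min_covered_fraction = 0.5,
                       strict = TRUE) {
  if (!(rfd_threshold > 0 && rfd_threshold <= 1)) {
    stop("rfd_threshold must lie in (0, 1]")
  }
  if (!(min_covered_fraction >= 0 && min_covered_fraction <= 1)) {
    stop("min_covered_fraction must lie in [0, 1]")
  }
  structure(list(rfd_threshold = rfd_threshold,
                 min_covered_fraction = min_covered_fraction,
                 strict = isTRUE(strict)),
            class = "trc_params")
}

#' Replication fork directionality from strand-resolved Okazaki counts
#'
#' Per bin, `RFD = (R - L) / (R + L)` where `R` and `L` are Okazaki
#' fragment counts assigned to rightward- and leftward-moving forks;
#' bins where `R + L = 0` (or either count is missing) are missing.
#'
#' @param right_counts,left_counts [signal_track()] objects with equal
#'   binsize and chromosome sets.
#' @return RFD [signal_track()] with values in `[-1, 1]`.
#' @export
compute_rfd <- function(right_counts, left_counts) {
  out <- .track_binop(right_counts, left_counts, function(r, l) {
    tot <- r + l
    ifelse(!is.na(tot) & tot > 0, (r - l) / tot, NA_real_)
  })
  signal_track(out$values, out$binsize, rfd = TRUE)
}

#' Map Watson/Crick Okazaki strand counts to rightward/leftward forks
#'
#' In the common OK-seq chemistry, fragments mapping to the Crick (minus)
#' strand derive from rightward-moving forks and Watson (plus) strand
#' fragments from leftward-moving forks.
#'
#' @param watson,crick strand count [signal_track()] objects.
#' @return list with elements `right` and `left`.
#' @export
okseq_strands_to_forks <- function(watson, crick) {
  list(right = crick, left = watson)
}

#' Mean RFD over an interval
#'
#' Length-weighted mean of the RFD track over the interval's non-missing
#' bins (partial bins weighted by base-pair overlap); missing when the
#' covered fraction falls below `min_covered_fraction`.
#'
#' @param interval one-row interval data.frame (or list with `chrom`,
#'   `start`, `end`).
#' @param rfd RFD [signal_track()].
#' @param min_covered_fraction coverage guard (default 0.5).
#' @return numeric scalar or `NA`.
#' @export
mean_rfd_over <- function(interval, rfd, min_covered_fraction = 0.5) {
  res <- track_window_means(rfd, interval$chrom[1], interval$start[1],
                            interval$end[1])
  if (is.na(res$mean[1]) || res$covered_fraction[1] < min_covered_fraction) {
    return(NA_real_)
  }
  res$mean[1]
}

#' Call directional transcription-replication conflict sites
#'
#' Retains stranded R-loop peaks whose mean RFD magnitude exceeds the
#' threshold and splits them by orientation: a peak is head-on when the
#' replication fork direction (sign of mean RFD) opposes the peak's
#' transcription strand, co-directional when they agree.
#'
#' @param rloop_peaks stranded interval data.frame (BED6 convention).
#' @param rfd RFD [signal_track()].
#' @param params a [trc_params()].
#' @return data.frame of TRC sites: peak columns plus `mean_rfd`,
#'   `fork_direction` (`"rightward"`/`"leftward"`) and `orientation`
#'   (`"head_on"`/`"codirectional"`), sorted. Attribute `report` counts
#'   peaks excluded for each reason.
#' @export
call_trcs <- function(rloop_peaks, rfd, params = trc_params()) {
  peaks <- validate_intervals(rloop_peaks, what = "R-loop peak")
  stopifnot(inherits(params, "trc_params"))
  n <- nrow(peaks)
  report <- c(unstranded = 0, missing_chrom = 0, low_coverage = 0,
              below_threshold = 0)
  if (n == 0) {
    out <- cbind(peaks, mean_rfd = numeric(0),
                 fork_direction = character(0), orientation = character(0))
    attr(out, "report") <- report
    return(out)
  }
  unstranded <- !peaks$strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sprintf("%d unstranded peak(s) skipped", sum(unstranded)))
    report["unstranded"] <- sum(unstranded)
  }
  off_track <- !peaks$chrom %in% track_chroms(rfd)
  if (any(off_track & !unstranded)) {
    report["missing_chrom"] <- sum(off_track & !unstranded)
  }
  mean_rfd <- rep(NA_real_, n)
  for (ch in intersect(unique(peaks$chrom), track_chroms(rfd))) {
    idx <- which(peaks$chrom == ch & !unstranded)
    if (!length(idx)) next
    res <- track_window_means(rfd, ch, peaks$start[idx], peaks$end[idx])
    m <- res$mean
    m[res$covered_fraction < params$min_covered_fraction] <- NA_real_
    mean_rfd[idx] <- m
  }
  usable <- !unstranded & !off_track
  report["low_coverage"] <- sum(usable & is.na(mean_rfd))
  pass <- usable & !is.na(mean_rfd) &
    if (params$strict) abs(mean_rfd) > params$rfd_threshold else
      abs(mean_rfd) >= params$rfd_threshold
  report["below_threshold"] <- sum(usable & !is.na(mean_rfd) & !pass)
  out <- peaks[pass, , drop = FALSE]
  out$mean_rfd <- mean_rfd[pass]
  out$fork_direction <- ifelse(out$mean_rfd > 0, "rightward", "leftward")
  out$orientation <- ifelse(
    (out$mean_rfd > 0 & out$strand == "-") |
      (out$mean_rfd < 0 & out$strand == "+"),
    "head_on", "codirectional")
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Write TRC sites as extended BED
#'
#' BED6 columns followed by `mean_rfd` and `orientation`.
#'
#' @param trcs TRC data.frame from [call_trcs()].
#' @param path output path.
#' @export
write_trcs <- function(trcs, path) {
  df <- trcs[, c("chrom", "start", "end", "name", "score", "strand")]
  df$mean_rfd <- sprintf("%.17g", trcs$mean_rfd)
  df$orientation <- trcs$orientation
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
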