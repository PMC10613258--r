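#' Count assigned mutations per signature in region sets
#'
#' @param assigned data.frame with `chrom`, `start` (0-based) and
#'   `signature` columns (e.g. a mutation table plus the labels from
#'   [assign_mutations()]).
#' @param region_sets named list of interval data.frames.
#' @return list: `counts` (signatures x sets matrix) and `totals`
#'   (mutations per set).
#' @export
region_signature_counts <- function(assigned, region_sets) {
  stopifnot(is.list(region_sets), !is.null(names(region_sets)))
  sigs <- sort(unique(assigned$signature))
  counts <- matrix(0L, length(sigs), length(region_sets),
                   dimnames = list(sigs, names(region_sets)))
  totals <- stats::setNames(integer(length(region_sets)), names(region_sets))
  for (nm in names(region_sets)) {
    inside <- points_in_intervals(assigned$chrom, assigned$start,
                                  region_sets[[nm]])
    totals[nm] <- sum(inside)
    if (any(inside)) {
      tb <- table(factor(assigned$signature[inside], levels = sigs))
      counts[, nm] <- as.integer(tb)
    }
  }
  list(counts = counts, totals = totals)
}

#' Risk ratio with 95\% Wald confidence interval
#'
#' `RR = (count_a/total_a) / (count_b/total_b)` with
#' `CI = exp(log RR +/- 1.96 * sqrt(1/count_a - 1/total_a + 1/count_b -
#' 1/total_b))`. Zero counts trigger a continuity correction (+0.5 to
#' every cell), flagged in the result.
#'
#' @param count_a,total_a events and trials in the exposed group.
#' @param count_b,total_b events and trials in the reference group.
#' @return list: `rr`, `ci_low`, `ci_high`, `corrected`.
#' @export
signature_risk_ratio <- function(count_a, total_a, count_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0")
  corrected <- count_a == 0 || count_b == 0
  if (corrected) {
    count_a <- count_a + 0.5; count_b <- count_b + 0.5
    total_a <- total_a + 0.5; total_b <- total_b + 0.5
  }
  rr <- (count_a / total_a) / (count_b / total_b)
  se <- sqrt(1 / count_a - 1 / total_a + 1 / count_b - 1 / total_b)
  list(rr = rr,
       ci_low = exp(log(rr) - 1.96 * se),
       ci_high = exp(log(rr) + 1.96 * se),
       corrected = corrected)
}

# pad intervals by +/- pad bp (clipped at 0) and intersect two interval
# sets, chromosome-wise
pad_intervals <- function(intervals, pad) {
  out <- intervals
  out$start <- pmax(0, out$start - pad)
  out$end <- out$end + pad
  validate_intervals(out)
}

intersect_intervals <- function(a, b) {
  res <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::reduce(.as_iranges(a[a$chrom == ch, ]))
    rb <- IRanges::reduce(.as_iranges(b[b$chrom == ch, ]))
    ri <- IRanges::intersect(ra, rb)
    if (length(ri)) {
      res[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(ri) - 1,
                              end = IRanges::end(ri))
    }
  }
  if (!length(res)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  out <- do.call(rbind, res)
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Factor-conditioned signature frequency log2 fold-changes
#'
#' For each chromatin factor, forms the regions where padded R-loops
#' (`+/- pad` bp) intersect that factor's peaks, computes the signature
#' frequency spectrum of assigned mutations inside them, and contrasts
#' it with the spectrum over all (padded) R-loop regions:
#' `log2(freq_s(factor) / freq_s(all))`. Zero frequencies are
#' continuity-corrected with +0.5 counts and flagged.
#'
#' @param assigned data.frame with `chrom`, `start`, `signature`.
#' @param factor_peak_sets named list of factor peak interval frames.
#' @param all_rloops R-loop peak intervals.
#' @param pad padding in bp applied to the R-loop regions
#'   (default 2500).
#' @return list: `logfc` (factors x signatures matrix, `NA` rows where
#'   a factor set caught no mutation), `corrected` (logical matrix),
#'   `n_mutations` (per factor).
#' @export
factor_signature_logfc <- function(assigned, factor_peak_sets, all_rloops,
                                   pad = 2500) {
  stopifnot(is.list(factor_peak_sets), !is.null(names(factor_peak_sets)))
  padded <- pad_intervals(all_rloops, pad)
  sigs <- sort(unique(assigned$signature))
  ref <- region_signature_counts(assigned, list(all = padded))
  ref_counts <- ref$counts[, "all"]
  ref_total <- ref$totals[["all"]]
  if (ref_total == 0) stop("no assigned mutation falls in the R-loop regions")
  logfc <- matrix(NA_real_, length(factor_peak_sets), length(sigs),
                  dimnames = list(names(factor_peak_sets), sigs))
  corrected <- matrix(FALSE, length(factor_peak_sets), length(sigs),
                      dimnames = dimnames(logfc))
  n_mut <- stats::setNames(integer(length(factor_peak_sets)),
                           names(factor_peak_sets))
  for (f in names(factor_peak_sets)) {
    regions <- intersect_intervals(padded, factor_peak_sets[[f]])
    rc <- region_signature_counts(assigned, list(f = regions))
    cf <- rc$counts[, "f"]; tf <- rc$totals[["f"]]
    n_mut[f] <- tf
    if (tf == 0) next
    for (s in sigs) {
      a <- cf[[s]]; b <- ref_counts[[s]]
      if (a == 0 || b == 0) {
        corrected[f, s] <- TRUE
        a <- a + 0.5; b <- b + 0.5
      }
      logfc[f, s] <- log2((a / tf) / (b / ref_total))
    }
  }
  list(logfc = logfc, corrected = corrected, n_mutations = n_mut)
}

#' Cluster factors by their signature-association profiles
#'
#' Agglomerative clustering of factor rows with distance
#' `1 - Pearson correlation` and average linkage, cut to `n_clusters`.
#' Rows with undefined correlation (constant profiles) or missing
#' values become singleton clusters and are reported.
#'
#' @param logfc_matrix factors x signatures numeric matrix.
#' @param n_clusters number of clusters (default 7).
#' @return list: `labels` (named integer vector), `tree` (`hclust` over
#'   the well-defined rows, or NULL), `singletons` (row names set
#'   aside).
#' @export
cluster_factors <- function(logfc_matrix, n_clusters = 7) {
  m <- as.matrix(logfc_matrix)
  if (is.null(rownames(m))) rownames(m) <- sprintf("f%d", seq_len(nrow(m)))
  usable <- apply(m, 1, function(r) all(is.finite(r)) && stats::sd(r) > 0)
  singles <- rownames(m)[!usable]
  mu <- m[usable, , drop = FALSE]
  labels <- stats::setNames(integer(nrow(m)), rownames(m))
  tree <- NULL
  if (nrow(mu) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(mu)))
    tree <- stats::hclust(d, method = "average")
    kk <- min(n_clusters, nrow(mu))
    labels[rownames(mu)] <- stats::cutree(tree, k = kk)
    next_label <- max(labels) + seq_along(singles)
  } else if (nrow(mu) == 1) {
    labels[rownames(mu)] <- 1L
    next_label <- 1 + seq_along(singles)
  } else {
    next_label <- seq_along(singles)
  }
  if (length(singles)) {
    labels[singles] <- next_label
    warning(sprintf("%d constant/incomplete row(s) assigned singleton clusters",
                    length(singles)))
  }
  list(labels = labels, tree = tree, singletons = singles)
}
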