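#' Parameters for hotspot calling
#'
#' Two-threshold broad-region semantics: maximal runs of bins at or
#' above `c_peak` seed hotspots; neighbouring seeds at most `max_gap`
#' apart are merged when every intervening bin is at or above the
#' linking cutoff `c_link`; merged regions shorter than `min_len` are
#' discarded.
#'
#' @param binsize density-track bin width in bp (default 1000).
#' @param c_peak primary (peak) cutoff (default 0.25).
#' @param c_link secondary (linking) cutoff (default `c_peak/2`).
#' @param min_len minimum hotspot length in bp (default 200).
#' @param max_gap maximum merged gap in bp (default 500).
#' @return list of class `hotspot_params`.
#' @export
hotspot_params <- function(binsize = 1000, c_peak = 0.25,
                           c_link = c_peak / 2, min_len = 200,
                           max_gap = 500) {
  if (c_link > c_peak) stop("c_link must be <= c_peak")
  if (min_len <= 0) stop("min_len must be > 0")
  if (binsize <= 0) stop("binsize must be > 0")
  structure(list(binsize = binsize, c_peak = c_peak, c_link = c_link,
                 min_len = min_len, max_gap = max_gap),
            class = "hotspot_params")
}

#' Mutation density track
#'
#' Bins mutations of one class by their 0-based start position and
#' scales counts to events per kilobase, so that
#' `sum(track) * binsize / 1000` equals the number of binned events.
#'
#' @param mutations mutation data.frame (see [read_mutations()]).
#' @param mut_class `"SNV"`, `"INS"` or `"DEL"`; `NULL` keeps all.
#' @param binsize bin width in bp (default 1000).
#' @param chrom_lengths named chromosome lengths (bp); defaults to the
#'   largest mutation position per chromosome.
#' @return a [signal_track()] (zero where covered, never missing).
#' @export
density_track <- function(mutations, mut_class = NULL, binsize = 1000,
                          chrom_lengths = NULL) {
  if (!is.null(mut_class)) {
    mutations <- mutations[mutations$mut_class == mut_class, , drop = FALSE]
  }
  if (is.null(chrom_lengths)) {
    if (nrow(mutations) == 0) stop("need chrom_lengths for an empty catalog")
    chrom_lengths <- tapply(mutations$pos, mutations$chrom, max)
  }
  vals <- lapply(names(chrom_lengths), function(ch) {
    nb <- as.integer(ceiling(chrom_lengths[[ch]] / binsize))
    p <- mutations$start[mutations$chrom == ch]
    p <- p[p < nb * binsize]
    counts <- tabulate(floor(p / binsize) + 1L, nbins = nb)
    counts * (1000 / binsize)
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, binsize)
}

#' Call mutation hotspots from a density track
#'
#' @param track a [signal_track()] binned at `params$binsize`.
#' @param params a [hotspot_params()].
#' @return interval data.frame of hotspots (half-open, on the bin grid),
#'   named `hotspot_1, ...` in genome order.
#' @export
call_hotspots <- function(track, params = hotspot_params()) {
  stopifnot(inherits(track, "signal_track"),
            inherits(params, "hotspot_params"))
  if (track$binsize != params$binsize) {
    stop("track binsize differs from params$binsize")
  }
  bs <- track$binsize
  gap_bins <- floor(params$max_gap / bs)
  res <- list()
  for (ch in track_chroms(track)) {
    v <- track$values[[ch]]
    v[is.na(v)] <- -Inf
    peak <- v >= params$c_peak
    if (!any(peak)) next
    r <- rle(peak)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(s = starts[r$values], e = ends[r$values])
    # merge runs whose gap is short enough and linkable throughout
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        last <- nrow(merged)
        gap <- (runs$s[k] - 1) - merged$e[last]
        linkable <- gap <= gap_bins &&
          (gap == 0 || all(v[(merged$e[last] + 1):(runs$s[k] - 1)] >=
                             params$c_link))
        if (linkable) merged$e[last] <- runs$e[k] else
          merged <- rbind(merged, runs[k, ])
      }
    }
    len <- (merged$e - merged$s + 1) * bs
    merged <- merged[len >= params$min_len, , drop = FALSE]
    if (nrow(merged)) {
      res[[ch]] <- data.frame(chrom = ch, start = (merged$s - 1) * bs,
                              end = merged$e * bs)
    }
  }
  if (!length(res)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- genomic_intervals(out$chrom, out$start, out$end)
  out$name <- sprintf("hotspot_%d", seq_len(nrow(out)))
  out
}

#' Classify genes by R-loop propensity and expression
#'
#' A gene overlapping at least one R-loop peak is `rloop_prone`
#' (regardless of expression); otherwise it is `expressed_reluctant`
#' when its expression exceeds the cutoff, else `silenced`.
#'
#' @param genes gene interval data.frame with an `expression` column
#'   (or numeric `score` used as expression).
#' @param rloop_peaks R-loop peak intervals.
#' @param expression_cutoff strict lower bound for "expressed"
#'   (default 0).
#' @return character vector of classes aligned with `genes` rows.
#' @export
classify_genes <- function(genes, rloop_peaks, expression_cutoff = 0) {
  genes <- validate_intervals(genes, what = "gene")
  expr <- if ("expression" %in% names(genes)) genes$expression else genes$score
  if (is.null(expr) || any(is.na(expr))) {
    stop("genes need an 'expression' (or score) column without NAs")
  }
  has_peak <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pk <- rloop_peaks[rloop_peaks$chrom == ch, , drop = FALSE]
    if (!nrow(pk)) next
    has_peak[gi] <- IRanges::overlapsAny(.as_iranges(genes[gi, ]),
                                         .as_iranges(pk))
  }
  ifelse(has_peak, "rloop_prone",
         ifelse(expr > expression_cutoff, "expressed_reluctant", "silenced"))
}

#' Associate hotspots with gene classes
#'
#' Each hotspot is assigned the class of the gene containing its
#' midpoint (`none` when intergenic). Reports per-class percentages over
#' all hotspots, pairwise 2x2 chi-square tests with Yates' continuity
#' correction of hotspot presence versus gene class, and an overall
#' r x c chi-square without correction.
#'
#' @param hotspots hotspot intervals (from [call_hotspots()]).
#' @param genes gene intervals.
#' @param gene_classes character vector from [classify_genes()].
#' @return list with `assignment` (per-hotspot class), `percentages`,
#'   `pairwise` (data.frame of Yates tests), `overall`
#'   (`htest`-like list), `excluded_classes`.
#' @export
hotspot_gene_association <- function(hotspots, genes, gene_classes) {
  if (nrow(hotspots) == 0) stop("need at least one hotspot")
  stopifnot(length(gene_classes) == nrow(genes))
  mids <- interval_midpoints(hotspots)
  gi <- point_interval_index(hotspots$chrom, mids, genes)
  assignment <- ifelse(is.na(gi), "none", gene_classes[gi])
  lev <- c("rloop_prone", "expressed_reluctant", "silenced")
  pct <- 100 * vapply(lev, function(cl) mean(assignment == cl), numeric(1))
  present <- tapply(seq_along(gene_classes), gene_classes, length)
  excluded <- setdiff(lev, names(present))
  lev_use <- setdiff(lev, excluded)
  gene_has <- tabulate(gi[!is.na(gi)], nbins = nrow(genes)) > 0
  tab <- table(factor(gene_classes, levels = lev_use),
               factor(gene_has, levels = c(TRUE, FALSE)))
  pairwise <- NULL
  if (length(lev_use) >= 2) {
    combs <- utils::combn(lev_use, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      t2 <- tab[combs[, k], , drop = FALSE]
      ht <- suppressWarnings(stats::chisq.test(t2, correct = TRUE))
      data.frame(class_a = combs[1, k], class_b = combs[2, k],
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value, stringsAsFactors = FALSE)
    }))
  }
  overall <- if (length(lev_use) >= 2) {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  } else {
    NULL
  }
  list(assignment = assignment, percentages = pct, pairwise = pairwise,
       overall = overall, excluded_classes = excluded, table = tab)
}

#' Per-site mutation rates by class
#'
#' Counts mutations whose 0-based start position lies in each half-open
#' site interval (deletions by their start only) and divides by site
#' length in kilobases. Overlapping sites count shared mutations once
#' per site.
#'
#' @param trc_sites site data.frame (any validated intervals).
#' @param mutations mutation data.frame.
#' @return data.frame: site columns plus `snv_per_kb`, `del_per_kb`,
#'   `ins_per_kb`, `length_kb`.
#' @export
site_rates <- function(trc_sites, mutations) {
  sites <- validate_intervals(trc_sites, what = "site")
  extra <- setdiff(names(trc_sites), names(sites))
  if (any(sites$end <= sites$start)) stop("zero-length site")
  counts <- matrix(0, nrow(sites), 3,
                   dimnames = list(NULL, c("SNV", "DEL", "INS")))
  for (cls in colnames(counts)) {
    mu <- mutations[mutations$mut_class == cls, , drop = FALSE]
    if (!nrow(mu)) next
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      p <- mu$start[mu$chrom == ch]
      if (!length(p)) next
      q <- IRanges::IRanges(start = p + 1L, width = 1L)
      counts[si, cls] <- IRanges::countOverlaps(.as_iranges(sites[si, ]), q)
    }
  }
  kb <- (sites$end - sites$start) / 1000
  out <- cbind(sites,
               data.frame(snv_per_kb = counts[, "SNV"] / kb,
                          del_per_kb = counts[, "DEL"] / kb,
                          ins_per_kb = counts[, "INS"] / kb,
                          length_kb = kb))
  out
}

#' Orientation comparison of per-site mutation-rate exceedance
#'
#' For each class, tabulates sites above/below the rate threshold by
#' orientation and tests head-on excess with a one-tailed Fisher exact
#' test (hypergeometric tail).
#'
#' @param rates output of [site_rates()] on sites carrying an
#'   `orientation` column.
#' @param thresholds named list/vector: `snv` (default 1.0), `del`
#'   (0.1), `ins` (0.1) in events per kb.
#' @return data.frame with one row per class: fraction above threshold
#'   per orientation, counts, and the one-tailed p-value.
#' @export
orientation_rate_comparison <- function(rates,
                                        thresholds = c(snv = 1.0, del = 0.1,
                                                       ins = 0.1)) {
  if (!"orientation" %in% names(rates)) {
    stop("rates need an orientation column")
  }
  ho <- rates$orientation == "head_on"
  cd <- rates$orientation == "codirectional"
  if (!any(ho) || !any(cd)) stop("both orientations must be present")
  cols <- c(snv = "snv_per_kb", del = "del_per_kb", ins = "ins_per_kb")
  out <- do.call(rbind, lapply(names(cols), function(cls) {
    v <- rates[[cols[[cls]]]]
    above <- v > thresholds[[cls]]
    tab <- matrix(c(sum(above & ho), sum(!above & ho),
                    sum(above & cd), sum(!above & cd)),
                  nrow = 2,
                  dimnames = list(c("above", "below"), c("HO", "CD")))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(class = toupper(cls), threshold = thresholds[[cls]],
               ho_fraction = mean(above[ho]), cd_fraction = mean(above[cd]),
               ho_above = sum(above & ho), ho_n = sum(ho),
               cd_above = sum(above & cd), cd_n = sum(cd),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tumor proficiency status for a chromatin gene
#'
#' A tumor is `deficient` when it carries at least one frameshift,
#' missense or nonsense mutation whose position lies inside the gene
#' interval; otherwise `proficient`.
#'
#' @param tumor_mutations mutation data.frame for one tumor.
#' @param gene_interval one-row interval data.frame.
#' @return `"proficient"` or `"deficient"`.
#' @export
classify_tumor_status <- function(tumor_mutations, gene_interval) {
  disrupting <- tumor_mutations$functional_class %in%
    c("frameshift", "missense", "nonsense")
  inside <- tumor_mutations$chrom == gene_interval$chrom[1] &
    tumor_mutations$start >= gene_interval$start[1] &
    tumor_mutations$start < gene_interval$end[1]
  if (any(disrupting & inside)) "deficient" else "proficient"
}

#' Parameters for the R-loop burden analysis
#'
#' @param min_mutations minimum catalog size for a tumor to be retained
#'   (default 1000).
#' @param normalize `"count"` (default) or `"per_kb"` of total peak span.
#' @return list of class `burden_params`.
#' @export
burden_params <- function(min_mutations = 1000,
                          normalize = c("count", "per_kb")) {
  normalize <- match.arg(normalize)
  if (min_mutations < 0) stop("min_mutations must be >= 0")
  structure(list(min_mutations = min_mutations, normalize = normalize),
            class = "burden_params")
}

#' Per-tumor R-loop mutation burden
#'
#' Tumors with fewer than `min_mutations` mutations are excluded; the
#' burden is the number of the tumor's mutations falling inside the
#' union of the R-loop peaks (so abutting or overlapping peaks never
#' double-count), optionally per kb of total peak span.
#'
#' @param mutations mutation data.frame for all tumors.
#' @param rloop_peaks R-loop peak intervals.
#' @param params a [burden_params()].
#' @param status_gene optional one-row gene interval; when given, each
#'   tumor's proficiency status for that gene is recorded.
#' @return data.frame with one row per retained tumor: `sample`,
#'   `n_mutations`, `burden`, and `status` when `status_gene` is given.
#' @export
rloop_burden <- function(mutations, rloop_peaks, params = burden_params(),
                         status_gene = NULL) {
  stopifnot(inherits(params, "burden_params"))
  peaks <- validate_intervals(rloop_peaks, what = "R-loop peak")
  n_by <- table(mutations$sample)
  keep <- names(n_by)[n_by >= params$min_mutations]
  mutations <- mutations[mutations$sample %in% keep, , drop = FALSE]
  inside <- points_in_intervals(mutations$chrom, mutations$start, peaks)
  burden <- tapply(inside, factor(mutations$sample, levels = keep), sum)
  burden[is.na(burden)] <- 0
  if (params$normalize == "per_kb") {
    span_kb <- sum(vapply(unique(peaks$chrom), function(ch) {
      r <- IRanges::reduce(.as_iranges(peaks[peaks$chrom == ch, ]))
      sum(IRanges::width(r))
    }, numeric(1))) / 1000
    if (span_kb == 0) stop("zero total peak span")
    burden <- burden / span_kb
  }
  out <- data.frame(sample = keep,
                    n_mutations = as.integer(n_by[keep]),
                    burden = as.numeric(burden),
                    stringsAsFactors = FALSE)
  if (!is.null(status_gene)) {
    out$status <- vapply(keep, function(s) {
      classify_tumor_status(mutations[mutations$sample == s, , drop = FALSE],
                            status_gene)
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

# Wilcoxon rank-sum: exact enumeration when both n <= 10 (valid with
# ties), otherwise tie-corrected normal approximation with continuity
# correction. Two-tailed.
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U of x
  if (nx <= exact_max && ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    nties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- (nx * ny / 12) *
      ((nx + ny + 1) - sum(nties^3 - nties) / ((nx + ny) * (nx + ny - 1)))
    z <- w - mu
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p_value = p, method = method, n = c(nx, ny))
}

#' Compare R-loop burden between proficient and deficient tumors
#'
#' Two-tailed Wilcoxon rank-sum test of per-tumor burden by status
#' (exact enumeration when both groups have at most 10 tumors, else a
#' tie-corrected normal approximation).
#'
#' @param statuses output of [rloop_burden()] with a `status` column.
#' @return list: `median_proficient`, `median_deficient`, `p_value`,
#'   `statistic`, `method`, `n`.
#' @export
burden_comparison <- function(statuses) {
  if (!"status" %in% names(statuses)) stop("statuses need a status column")
  prof <- statuses$burden[statuses$status == "proficient"]
  defi <- statuses$burden[statuses$status == "deficient"]
  if (!length(prof)) stop("group 'proficient' is empty")
  if (!length(defi)) stop("group 'deficient' is empty")
  ht <- wilcoxon_rank_sum(defi, prof)
  list(median_proficient = stats::median(prof),
       median_deficient = stats::median(defi),
       p_value = ht$p_value, statistic = ht$statistic,
       method = ht$method, n = c(deficient = length(defi),
                                 proficient = length(prof)))
}

#' Randomize intervals within their host genes
#'
#' Re-places each interval uniformly at random within the gene that
#' contains it, preserving interval length (the within-gene shuffling
#' control for burden analyses). Intervals longer than their host gene
#' are kept in place and reported.
#'
#' @param intervals interval data.frame.
#' @param host_genes gene intervals; each interval must be contained in
#'   exactly one (assignment by interval midpoint).
#' @param seed RNG seed.
#' @return shuffled intervals (same rows/order); attribute `kept`
#'   lists rows left untouched.
#' @export
shuffle_within_genes <- function(intervals, host_genes, seed = 1) {
  intervals <- validate_intervals(intervals)
  host_genes <- validate_intervals(host_genes, what = "gene")
  gi <- point_interval_index(intervals$chrom, interval_midpoints(intervals),
                             host_genes)
  if (any(is.na(gi))) {
    stop("every interval must lie within a host gene")
  }
  set.seed(seed)
  len <- intervals$end - intervals$start
  room <- (host_genes$end[gi] - host_genes$start[gi]) - len
  kept <- which(room < 0)
  out <- intervals
  mv <- which(room >= 0)
  offs <- floor(stats::runif(length(mv)) * (room[mv] + 1))
  out$start[mv] <- host_genes$start[gi[mv]] + offs
  out$end[mv] <- out$start[mv] + len[mv]
  if (length(kept)) {
    warning(sprintf("%d interval(s) longer than their host gene kept in place",
                    length(kept)))
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- kept
  out
}

#' Percentage of overlapping features
#'
#' @param total total feature count (> 0).
#' @param overlap overlapping feature count, `0 <= overlap <= total`.
#' @return `100 * overlap / total`, rounded to one decimal.
#' @export
overlap_percentage <- function(total, overlap) {
  if (length(total) != 1 || length(overlap) != 1) {
    stop("total and overlap must be scalars")
  }
  if (total <= 0) stop("total must be > 0")
  if (overlap < 0 || overlap > total) {
    stop("overlap must lie in [0, total]")
  }
  round(100 * overlap / total, 1)
}
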