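#' Parameters for the factor enrichment screen
#'
#' Defaults mirror the center-versus-flank design used throughout the
#' package: signal over +/-10 kb around the site midpoint compared with
#' 20 kb windows centered at -1 Mb (upstream of the incoming fork) and
#' +1 Mb (downstream).
#'
#' @param center_halfwidth half-width of the center window in bp
#'   (default 10000).
#' @param flank_width width of each flank window in bp (default 20000).
#' @param flank_offset distance from site midpoint to flank center in bp
#'   (default 1e6).
#' @param window_halfwidth half-width of full profile windows in bp
#'   (default 1e6).
#' @param rms_cutoff hit threshold on |RMS| (default 0.25).
#' @param orient_by `"fork"` (flip by replication direction),
#'   `"transcription"` (flip by peak strand) or `"none"`.
#' @param stat `"mean"` (default) or `"median"` across per-site window
#'   means.
#' @return list of class `screen_params`.
#' @export
screen_params <- function(center_halfwidth = 10000, flank_width = 20000,
                          flank_offset = 1e6, window_halfwidth = 1e6,
                          rms_cutoff = 0.25,
                          orient_by = c("fork", "transcription", "none"),
                          stat = c("mean", "median")) {
  orient_by <- match.arg(orient_by)
  stat <- match.arg(stat)
  if (rms_cutoff <= 0) stop("rms_cutoff must be > 0")
  if (flank_offset < center_halfwidth + flank_width / 2) {
    stop("flank_offset must be >= center_halfwidth + flank_width/2")
  }
  structure(list(center_halfwidth = center_halfwidth,
                 flank_width = flank_width, flank_offset = flank_offset,
                 window_halfwidth = window_halfwidth,
                 rms_cutoff = rms_cutoff, orient_by = orient_by,
                 stat = stat),
            class = "screen_params")
}

# per-site flip indicator for a chosen orientation mode
.site_flip <- function(sites, orient_by) {
  switch(orient_by,
    none = rep(FALSE, nrow(sites)),
    transcription = {
      if (!"strand" %in% names(sites)) stop("sites lack a strand column")
      sites$strand == "-"
    },
    fork = {
      if (!"fork_direction" %in% names(sites)) {
        stop("orient_by='fork' needs a fork_direction column (see call_trcs)")
      }
      sites$fork_direction == "leftward"
    },
    stop(sprintf("unknown orientation mode '%s'", orient_by)))
}

#' Site-by-bin coverage matrix around site midpoints
#'
#' Each retained site contributes one row: the track resampled onto
#' `nbins` equal bins spanning `[midpoint - window, midpoint + window)`
#' by length-weighted averaging. Rows of leftward-fork (or minus-strand)
#' sites are reversed in place so that "upstream" is always to the left.
#' Sites whose window is truncated by a chromosome edge (or whose
#' chromosome is absent from the track) are dropped and reported.
#'
#' @param sites interval data.frame (TRC sites for oriented modes).
#' @param track a [signal_track()].
#' @param window_halfwidth window half-width in bp.
#' @param nbins even number of profile bins.
#' @param orient_by `"fork"`, `"transcription"` or `"none"`.
#' @return `profile_matrix`: sites x bins matrix with attributes
#'   `bin_centers` (bp offsets from the site midpoint), `site_index`
#'   (rows of `sites` retained) and `dropped` (rows excluded).
#' @export
coverage_matrix <- function(sites, track, window_halfwidth = 1e6,
                            nbins = 200, orient_by = "none") {
  sites <- validate_intervals(sites, what = "site")
  if (nrow(sites) == 0) stop("empty site list")
  if (nbins %% 2 != 0 || nbins < 2) stop("nbins must be even and >= 2")
  flip <- .site_flip(sites, orient_by)
  mids <- interval_midpoints(sites)
  keep <- logical(nrow(sites))
  rows <- vector("list", nrow(sites))
  binw <- 2 * window_halfwidth / nbins
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (!ch %in% track_chroms(track)) next
    L <- track_chrom_length(track, ch)
    ok <- idx[mids[idx] - window_halfwidth >= 0 &
              mids[idx] + window_halfwidth <= L]
    if (!length(ok)) next
    I <- .st_integrator(track$values[[ch]], track$binsize)
    for (s in ok) {
      edges <- mids[s] - window_halfwidth + binw * (0:nbins)
      ints <- I(edges)
      dv <- diff(ints$val); dc <- diff(ints$cov)
      row <- ifelse(dc > 0, dv / dc, NA_real_)
      if (flip[s]) row <- rev(row)
      rows[[s]] <- row
      keep[s] <- TRUE
    }
  }
  m <- do.call(rbind, rows[keep])
  if (is.null(m)) stop("no site survives the chromosome-edge filter")
  structure(m,
            bin_centers = -window_halfwidth + binw * (seq_len(nbins) - 0.5),
            site_index = which(keep), dropped = which(!keep),
            orient_by = orient_by, class = c("profile_matrix", "matrix"))
}

#' Column-wise mean profile of a coverage matrix
#'
#' @param matrix a `profile_matrix` (or any numeric matrix).
#' @return data.frame with per-bin `mean`, `se` (over non-missing rows)
#'   and `n`; `bin_center` when available.
#' @export
metaprofile <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) == 0) stop("nonempty matrix required")
  n <- colSums(!is.na(matrix))
  mu <- ifelse(n > 0, colMeans(matrix, na.rm = TRUE), NA_real_)
  sd <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1, sd / sqrt(n), NA_real_)
  out <- data.frame(mean = mu, se = se, n = n)
  bc <- attr(matrix, "bin_centers")
  if (!is.null(bc)) out <- cbind(bin_center = bc, out)
  rownames(out) <- NULL
  out
}

#' Plot a mean profile
#'
#' @param x output of [metaprofile()] (or [metagene()]).
#' @param ... passed to [graphics::plot()].
#' @export
plot_profile <- function(x, ...) {
  xs <- if ("bin_center" %in% names(x)) x$bin_center else seq_len(nrow(x))
  graphics::plot(xs, x$mean, type = "l",
                 xlab = "position (bp)", ylab = "mean signal", ...)
  if (all(c("se") %in% names(x))) {
    graphics::lines(xs, x$mean + x$se, lty = 3)
    graphics::lines(xs, x$mean - x$se, lty = 3)
  }
  invisible(x)
}

#' Scaled metagene profile
#'
#' Each gene body is rescaled to `body_bins` bins by length-weighted
#' averaging; fixed-width flanks of `flank_bp` are split into
#' `flank_bins` bins each and appended. Minus-strand gene profiles are
#' reversed so all run 5' to 3'. The mean across genes is returned.
#'
#' @param genes stranded interval data.frame.
#' @param track a [signal_track()].
#' @param body_bins bins across the gene body (default 60).
#' @param flank_bp flank width in bp (default 2000).
#' @param flank_bins bins per flank (default 20).
#' @return data.frame with `position` (bin label: negative upstream,
#'   0..1 scaled body, >1 downstream), `mean`, `se`, `n` and a `segment`
#'   column in `upstream/body/downstream`.
#' @export
metagene <- function(genes, track, body_bins = 60, flank_bp = 2000,
                     flank_bins = 20) {
  genes <- validate_intervals(genes, what = "gene")
  if (nrow(genes) == 0) stop("empty gene list")
  if (any(!genes$strand %in% c("+", "-"))) stop("genes must be stranded")
  total <- flank_bins + body_bins + flank_bins
  rows <- vector("list", nrow(genes))
  for (ch in unique(genes$chrom)) {
    if (!ch %in% track_chroms(track)) next
    I <- .st_integrator(track$values[[ch]], track$binsize)
    for (g in which(genes$chrom == ch)) {
      up <- seq(genes$start[g] - flank_bp, genes$start[g],
                length.out = flank_bins + 1)
      body <- seq(genes$start[g], genes$end[g], length.out = body_bins + 1)
      down <- seq(genes$end[g], genes$end[g] + flank_bp,
                  length.out = flank_bins + 1)
      edges <- c(up[-length(up)], body, down[-1])
      ints <- I(edges)
      dv <- diff(ints$val); dc <- diff(ints$cov)
      row <- ifelse(dc > 0, dv / dc, NA_real_)
      if (genes$strand[g] == "-") row <- rev(row)
      rows[[g]] <- row
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no gene overlaps the track's chromosomes")
  m <- do.call(rbind, rows)
  n <- colSums(!is.na(m))
  mu <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sd <- apply(m, 2, stats::sd, na.rm = TRUE)
  pos <- c(-rev(seq_len(flank_bins)) / flank_bins,
           (seq_len(body_bins) - 0.5) / body_bins,
           1 + seq_len(flank_bins) / flank_bins)
  data.frame(position = pos,
             segment = rep(c("upstream", "body", "downstream"),
                           c(flank_bins, body_bins, flank_bins)),
             mean = mu, se = ifelse(n > 1, sd / sqrt(n), NA_real_), n = n)
}

# per-site oriented window means for center and both flanks
.screen_windows <- function(sites, track, params) {
  flip <- .site_flip(sites, params$orient_by)
  mids <- interval_midpoints(sites)
  n <- nrow(sites)
  center <- up <- down <- rep(NA_real_, n)
  ok <- logical(n)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (!ch %in% track_chroms(track)) next
    L <- track_chrom_length(track, ch)
    lo <- mids[idx] - params$flank_offset - params$flank_width / 2
    hi <- mids[idx] + params$flank_offset + params$flank_width / 2
    idx <- idx[lo >= 0 & hi <= L]
    if (!length(idx)) next
    m <- mids[idx]
    cw <- track_window_means(track, ch, m - params$center_halfwidth,
                             m + params$center_halfwidth)$mean
    left <- track_window_means(track, ch,
                               m - params$flank_offset - params$flank_width / 2,
                               m - params$flank_offset + params$flank_width / 2)$mean
    right <- track_window_means(track, ch,
                                m + params$flank_offset - params$flank_width / 2,
                                m + params$flank_offset + params$flank_width / 2)$mean
    f <- flip[idx]
    center[idx] <- cw
    up[idx] <- ifelse(f, right, left)
    down[idx] <- ifelse(f, left, right)
    ok[idx] <- TRUE
  }
  list(center = center, up = up, down = down, retained = ok)
}

#' Center-versus-flank Rank Metric Score for one factor track
#'
#' Pools oriented per-site window means (center +/-10 kb; 20 kb flanks
#' at +/-1 Mb by default), then scores
#' `rms_up = log2(center / upstream flank)` and `rms_down` likewise.
#' A factor is `enriched` when both scores exceed `rms_cutoff`,
#' `depleted` when both fall below `-rms_cutoff`, otherwise `none`.
#'
#' @param sites TRC site data.frame (needs `fork_direction` for the
#'   default fork orientation).
#' @param track factor coverage [signal_track()] (non-negative).
#' @param params a [screen_params()].
#' @param factor_name label carried into the result.
#' @return one-row data.frame of class `factor_result`: `factor`,
#'   `rms_up`, `rms_down`, `klass`, `center`, `up_flank`, `down_flank`,
#'   `n_sites`, `unscorable`.
#' @export
screen_factor <- function(sites, track, params = screen_params(),
                          factor_name = "factor") {
  stopifnot(inherits(params, "screen_params"))
  w <- .screen_windows(sites, track, params)
  if (!any(w$retained)) stop("no site survives coverage windows")
  agg <- if (params$stat == "median") {
    function(x) stats::median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  center <- agg(w$center[w$retained])
  up <- agg(w$up[w$retained])
  down <- agg(w$down[w$retained])
  unscorable <- is.na(center) || is.na(up) || is.na(down) ||
    up <= 0 || down <= 0 || center < 0
  rms_up <- if (unscorable) NA_real_ else log2(center / up)
  rms_down <- if (unscorable) NA_real_ else log2(center / down)
  klass <- if (unscorable) {
    "none"
  } else if (rms_up > params$rms_cutoff && rms_down > params$rms_cutoff) {
    "enriched"
  } else if (rms_up < -params$rms_cutoff && rms_down < -params$rms_cutoff) {
    "depleted"
  } else {
    "none"
  }
  out <- data.frame(factor = factor_name, rms_up = rms_up,
                    rms_down = rms_down, klass = klass, center = center,
                    up_flank = up, down_flank = down,
                    n_sites = sum(w$retained), unscorable = unscorable,
                    stringsAsFactors = FALSE)
  class(out) <- c("factor_result", class(out))
  out
}

#' Screen a collection of factor tracks
#'
#' @param sites TRC site data.frame.
#' @param tracks named list of [signal_track()] objects.
#' @param params a [screen_params()].
#' @return data.frame with one [screen_factor()] row per track.
#' @export
screen_factors <- function(sites, tracks, params = screen_params()) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  out <- do.call(rbind, lapply(names(tracks), function(nm) {
    screen_factor(sites, tracks[[nm]], params, factor_name = nm)
  }))
  rownames(out) <- NULL
  out
}

#' Head-on versus co-directional mean factor abundance
#'
#' Compares the center-window mean signal between head-on and
#' co-directional TRC sites.
#'
#' @param sites TRC site data.frame with an `orientation` column.
#' @param track factor [signal_track()].
#' @param params a [screen_params()].
#' @return list with `ho_mean`, `cd_mean`, `delta` (`ho - cd`),
#'   `se_delta` (two-sample SE), `n_ho`, `n_cd`.
#' @export
compare_orientations <- function(sites, track, params = screen_params()) {
  if (!"orientation" %in% names(sites)) {
    stop("sites lack an orientation column (see call_trcs)")
  }
  w <- .screen_windows(sites, track, params)
  keep <- w$retained & !is.na(w$center)
  grp <- function(o) w$center[keep & sites$orientation == o]
  ho <- grp("head_on"); cd <- grp("codirectional")
  stat <- function(x) {
    if (!length(x)) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  sh <- stat(ho); sc <- stat(cd)
  delta <- if (length(ho) && length(cd)) sh["mean"] - sc["mean"] else NA_real_
  list(ho_mean = unname(sh["mean"]), cd_mean = unname(sc["mean"]),
       delta = unname(delta),
       se_delta = unname(sqrt(sh["se"]^2 + sc["se"]^2)),
       n_ho = length(ho), n_cd = length(cd))
}

#' Weighted Kolmogorov-Smirnov set enrichment score
#'
#' Running-sum enrichment of a member set in a metric-ranked list:
#' hits increment proportionally to `|metric|^weight_p` (normalized),
#' misses decrement by `1/(N - Nh)`; the score is the extremum of the
#' walk. The p-value is the add-one-corrected fraction of seeded set
#' label permutations with `|ES|` at least as large.
#'
#' @param ranked_factors named numeric vector of metrics (names are
#'   factor identifiers); ranked internally by decreasing metric.
#' @param member_set character vector, subset of the names.
#' @param weight_p hit weight exponent (default 1).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class `gene_set_result`: `es`, `p_value`, `n_perm`,
#'   `seed`, `set_size`, `n`.
#' @export
enrichment_score <- function(ranked_factors, member_set, weight_p = 1,
                             n_perm = 1000, seed = 1) {
  if (!length(member_set)) stop("empty member_set")
  if (is.null(names(ranked_factors))) stop("ranked_factors must be named")
  if (!all(member_set %in% names(ranked_factors))) {
    stop("member_set must be a subset of the ranked factor names")
  }
  if (!all(is.finite(ranked_factors))) stop("metrics must be finite")
  ord <- order(ranked_factors, decreasing = TRUE)
  metrics <- ranked_factors[ord]
  is_hit <- names(metrics) %in% member_set
  walk_es <- function(hit) {
    N <- length(metrics); Nh <- sum(hit)
    if (Nh == 0 || Nh == N) return(NA_real_)
    w <- abs(metrics)^weight_p
    hw <- sum(w[hit])
    inc <- if (hw > 0) ifelse(hit, w / hw, -1 / (N - Nh)) else
      ifelse(hit, 1 / Nh, -1 / (N - Nh))
    walk <- cumsum(inc)
    unname(walk[which.max(abs(walk))])
  }
  es <- walk_es(is_hit)
  set.seed(seed)
  Nh <- sum(is_hit)
  perm <- replicate(n_perm, {
    h <- logical(length(metrics))
    h[sample.int(length(metrics), Nh)] <- TRUE
    walk_es(h)
  })
  p <- (1 + sum(abs(perm) >= abs(es), na.rm = TRUE)) / (n_perm + 1)
  structure(list(es = es, p_value = p, n_perm = n_perm, seed = seed,
                 set_size = Nh, n = length(metrics)),
            class = "gene_set_result")
}

#' @method print gene_set_result
#' @export
print.gene_set_result <- function(x, ...) {
  cat(sprintf("set enrichment: ES = %.4f, p = %.4g (%d permutations, set %d/%d)\n",
              x$es, x$p_value, x$n_perm, x$set_size, x$n))
  invisible(x)
}

#' Aggregate contact submatrices around sites
#'
#' Extracts, per site, the square contact submatrix spanning
#' `+/-window_halfwidth` around the site's bin, rotates it 180 degrees
#' for leftward-fork sites (so upstream of the fork is always on the
#' left/top), and averages element-wise across sites. Sites too close
#' to a chromosome edge are dropped and reported.
#'
#' @param sites TRC site data.frame.
#' @param contacts a [contact_map()].
#' @param window_halfwidth window half-width in bp (default 2e6).
#' @param orient_by `"fork"`, `"transcription"` or `"none"`.
#' @return mean submatrix with attributes `n_sites`, `dropped`,
#'   `offsets` (bp of each bin center relative to the site).
#' @export
aggregate_contacts <- function(sites, contacts, window_halfwidth = 2e6,
                               orient_by = "fork") {
  stopifnot(inherits(contacts, "contact_map"))
  bs <- contacts$binsize
  if (window_halfwidth %% bs != 0) {
    stop("contact binsize must divide window_halfwidth")
  }
  hw <- as.integer(window_halfwidth / bs)
  flip <- .site_flip(sites, orient_by)
  mids <- interval_midpoints(sites)
  acc <- matrix(0, 2 * hw + 1, 2 * hw + 1)
  n_used <- 0
  dropped <- integer(0)
  for (s in seq_len(nrow(sites))) {
    m <- contacts$matrices[[sites$chrom[s]]]
    if (is.null(m)) { dropped <- c(dropped, s); next }
    b <- floor(mids[s] / bs) + 1
    if (b - hw < 1 || b + hw > nrow(m)) { dropped <- c(dropped, s); next }
    sub <- as.matrix(m[(b - hw):(b + hw), (b - hw):(b + hw)])
    if (flip[s]) sub <- sub[rev(seq_len(nrow(sub))), rev(seq_len(ncol(sub)))]
    acc <- acc + sub
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no site usable for contact aggregation")
  out <- acc / n_used
  attr(out, "n_sites") <- n_used
  attr(out, "dropped") <- dropped
  attr(out, "offsets") <- bs * (-hw:hw)
  out
}

#' Annotate peaks by position relative to gene models
#'
#' Assigns each peak, by its midpoint, to one of `promoter`
#' (TSS +/- `promoter_bp`), `five_prime` (first `five_prime_bp` of the
#' gene body), `body`, or `intergenic`, with precedence in that order.
#' Overlapping genes are resolved by category precedence, then nearest
#' TSS.
#'
#' @param peaks interval data.frame.
#' @param genes stranded gene interval data.frame.
#' @param promoter_bp promoter half-width around the TSS (default 1000).
#' @param five_prime_bp length of the 5' gene-body zone (default 2000).
#' @return character vector of categories, one per peak row.
#' @export
annotate_peaks <- function(peaks, genes, promoter_bp = 1000,
                           five_prime_bp = 2000) {
  peaks <- validate_intervals(peaks, what = "peak")
  genes <- validate_intervals(genes, what = "gene")
  if (any(!genes$strand %in% c("+", "-"))) stop("genes must be stranded")
  mids <- interval_midpoints(peaks)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  out <- rep("intergenic", nrow(peaks))
  rank <- c(promoter = 3, five_prime = 2, body = 1)
  for (p in seq_len(nrow(peaks))) {
    g <- which(genes$chrom == peaks$chrom[p])
    if (!length(g)) next
    mid <- mids[p]
    d_tss <- abs(mid - tss[g])
    in_prom <- d_tss <= promoter_bp
    in_body <- mid >= genes$start[g] & mid < genes$end[g]
    from_tss <- ifelse(genes$strand[g] == "+", mid - genes$start[g],
                       genes$end[g] - 1 - mid)
    in_five <- in_body & from_tss < five_prime_bp
    cat_g <- ifelse(in_prom, "promoter",
                    ifelse(in_five, "five_prime",
                           ifelse(in_body, "body", NA_character_)))
    hit <- which(!is.na(cat_g))
    if (!length(hit)) next
    best <- hit[order(-rank[cat_g[hit]], d_tss[hit])][1]
    out[p] <- cat_g[best]
  }
  out
}

#' GC content of an interval
#'
#' `(#G + #C) / (#A + #C + #G + #T)` over the interval; `N` bases are
#' excluded from numerator and denominator. Missing when no informative
#' base remains.
#'
#' @param sequence named character vector from [read_sequence()].
#' @param interval one-row interval data.frame.
#' @return fraction in `[0, 1]` or `NA`.
#' @export
gc_content <- function(sequence, interval) {
  seq <- sequence[[interval$chrom[1]]]
  if (is.null(seq)) stop(sprintf("chromosome '%s' absent from sequence",
                                 interval$chrom[1]))
  if (interval$end[1] > nchar(seq)) stop("interval exceeds sequence length")
  sub <- substr(seq, interval$start[1] + 1, interval$end[1])
  bases <- strsplit(sub, "")[[1]]
  informative <- bases %in% c("A", "C", "G", "T")
  if (!any(informative)) return(NA_real_)
  sum(bases %in% c("G", "C")) / sum(informative)
}
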