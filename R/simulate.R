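#' Configuration for the synthetic-genome bundle
#'
#' Encodes every planted parameter of the synthetic study system:
#' genome and gene geometry, expression, replication origins, R-loop
#' propensity, factor-track effects, tumor mutation process and
#' chromatin contacts. Identical configurations (including `seed`)
#' produce byte-identical bundles.
#'
#' @param seed master RNG seed.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_genes total gene count (allocated across chromosomes by
#'   length).
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (bp).
#' @param silenced_fraction fraction of genes with zero expression.
#' @param expression_meanlog,expression_sdlog log-normal expression
#'   parameters for expressed genes.
#' @param origin_spacing mean of the exponential inter-origin gaps (bp).
#' @param terminus_width width of the linear RFD ramp across each
#'   termination midpoint (bp).
#' @param rloop_max,rloop_halfsat R-loop probability per gene:
#'   `rloop_max * expr / (expr + rloop_halfsat)` (monotone in
#'   expression; 0 for silenced genes).
#' @param rloop_width_meanlog,rloop_width_sdlog log-normal R-loop peak
#'   width parameters (median 1 kb by default).
#' @param edge_margin minimum distance of gene bodies from chromosome
#'   ends (bp); keep at >= flank_offset + flank_width when the bundle
#'   feeds the +/-1 Mb factor screen.
#' @param gc_background,gc_gene GC content outside/inside gene bodies.
#' @param rfd_binsize,factor_binsize track bin sizes (bp).
#' @param trc_threshold |RFD| threshold used for the truth orientation
#'   table (default 0.75).
#' @param factor_specs named list; each element a list with
#'   `center_fold`, `flank_level`, `noise_cv`, `orientation_bias`
#'   (multiplier applied on top of `center_fold` at head-on sites).
#'   See [make_factor_specs()].
#' @param signature_defs channels x signatures probability matrix
#'   (columns sum to 1). Channel rownames are SBS96 labels and/or 1-bp
#'   ID83 labels (`"1:Del:C:0"` style).
#' @param tumor_specs list: `n_tumors`, `mutations_per_tumor` (fixed
#'   count), `signature_mixture` (signatures x tumors matrix, or one
#'   vector recycled), `ho_rate_multiplier` (>= 1), `deficient_fraction`,
#'   `target_gene`, `burden_multiplier` (R-loop rate multiplier in
#'   deficient tumors).
#' @param contact_spec list: `binsize` (default 10000), `alpha`
#'   (power-law decay exponent, > 0), `upstream_compaction_fold`
#'   applied 0.2-1 Mb upstream (fork-wise) of head-on sites.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              chrom_lengths = c(chrA = 4e6, chrB = 4e6),
                              n_genes = 600,
                              gene_length_meanlog = log(3000),
                              gene_length_sdlog = 0.4,
                              silenced_fraction = 0.3,
                              expression_meanlog = log(10),
                              expression_sdlog = 1,
                              origin_spacing = 150000,
                              terminus_width = 30000,
                              rloop_max = 0.9,
                              rloop_halfsat = 2,
                              rloop_width_meanlog = log(1000),
                              rloop_width_sdlog = 0.35,
                              edge_margin = 1.05e6,
                              gc_background = 0.5,
                              gc_gene = 0.5,
                              rfd_binsize = 1000,
                              factor_binsize = 1000,
                              trc_threshold = 0.75,
                              factor_specs = list(),
                              signature_defs = NULL,
                              tumor_specs = list(n_tumors = 0),
                              contact_spec = list(binsize = 10000,
                                                  alpha = 1,
                                                  upstream_compaction_fold = 1)) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = n_genes,
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              silenced_fraction = silenced_fraction,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              origin_spacing = origin_spacing,
              terminus_width = terminus_width,
              rloop_max = rloop_max, rloop_halfsat = rloop_halfsat,
              rloop_width_meanlog = rloop_width_meanlog,
              rloop_width_sdlog = rloop_width_sdlog,
              edge_margin = edge_margin,
              gc_background = gc_background, gc_gene = gc_gene,
              rfd_binsize = rfd_binsize, factor_binsize = factor_binsize,
              trc_threshold = trc_threshold,
              factor_specs = factor_specs,
              signature_defs = signature_defs,
              tumor_specs = tumor_specs,
              contact_spec = contact_spec)
  validate_simulation_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg list with [simulation_config()] fields.
#' @return the config, classed `simulation_config`.
#' @export
validate_simulation_config <- function(cfg) {
  probs <- c(cfg$silenced_fraction, cfg$rloop_max, cfg$gc_background,
             cfg$gc_gene)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0)) {
    stop("chrom_lengths must be a named vector of positive lengths")
  }
  ts <- cfg$tumor_specs
  if (!is.null(ts$ho_rate_multiplier) && any(ts$ho_rate_multiplier < 1)) {
    stop("ho_rate_multiplier must be >= 1")
  }
  if (!is.null(ts$deficient_fraction) &&
      (ts$deficient_fraction < 0 || ts$deficient_fraction > 1)) {
    stop("deficient_fraction must lie in [0, 1]")
  }
  if (!is.null(cfg$signature_defs)) {
    sd <- as.matrix(cfg$signature_defs)
    if (any(sd < 0)) stop("signature probabilities must be >= 0")
    if (any(abs(colSums(sd) - 1) > 1e-6)) {
      stop("signature definition columns must sum to 1")
    }
  }
  if (!is.null(cfg$contact_spec$alpha) && cfg$contact_spec$alpha <= 0) {
    stop("contact decay exponent alpha must be > 0")
  }
  structure(cfg, class = "simulation_config")
}

#' Convenience builder for factor-track specifications
#'
#' @param n number of factors.
#' @param center_fold planted center/flank fold (1 = null).
#' @param flank_level background mean level.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param orientation_bias extra fold at head-on sites.
#' @param prefix name prefix.
#' @return named list of factor specs; each carries a `planted_class`
#'   of `enriched`, `depleted` or `none`.
#' @export
make_factor_specs <- function(n, center_fold = 1, flank_level = 1,
                              noise_cv = 0.1, orientation_bias = 1,
                              prefix = "factor") {
  specs <- lapply(seq_len(n), function(i) {
    list(center_fold = center_fold, flank_level = flank_level,
         noise_cv = noise_cv, orientation_bias = orientation_bias,
         planted_class = if (center_fold > 1) "enriched" else
           if (center_fold < 1) "depleted" else "none")
  })
  names(specs) <- sprintf("%s_%d", prefix, seq_len(n))
  specs
}

# analytic RFD of the origin/terminus model at base positions x:
# +1 right of an origin, -1 left of the next one, linear ramp of width
# `terminus_width` (clamped to the gap) across the midpoint.
.rfd_at <- function(x, origins, terminus_width) {
  if (!length(origins)) return(rep(NA_real_, length(x)))
  origins <- sort(origins)
  i <- findInterval(x, origins)
  out <- numeric(length(x))
  out[i == 0] <- -1
  out[i == length(origins)] <- 1
  mid <- which(i > 0 & i < length(origins))
  if (length(mid)) {
    o1 <- origins[i[mid]]; o2 <- origins[i[mid] + 1]
    m <- (o1 + o2) / 2
    w <- pmin(terminus_width, o2 - o1)
    v <- 1 - 2 * (x[mid] - (m - w / 2)) / w
    out[mid] <- pmin(1, pmax(-1, v))
  }
  out
}

#' Synthetic replication fork directionality from origin positions
#'
#' RFD is +1 immediately right of an origin and -1 immediately left of
#' the next, with a linear ramp across the termination midpoint between
#' adjacent origins (0 exactly at the midpoint); per-bin values are the
#' ramp evaluated at bin midpoints.
#'
#' @param origins origin base positions (within the chromosome).
#' @param chrom_len chromosome length (bp).
#' @param binsize bin width (bp).
#' @param terminus_width ramp width (bp); clamped to each inter-origin
#'   gap.
#' @return numeric per-bin vector (all `NA` when `origins` is empty).
#' @export
simulate_rfd <- function(origins, chrom_len, binsize,
                         terminus_width = 30000) {
  if (any(origins < 0 | origins > chrom_len)) {
    stop("origins must lie within the chromosome")
  }
  nb <- as.integer(ceiling(chrom_len / binsize))
  centers <- (seq_len(nb) - 0.5) * binsize
  .rfd_at(centers, origins, terminus_width)
}

#' Synthetic factor coverage track with planted center effects
#'
#' Background bins have mean `flank_level` with multiplicative
#' log-normal noise of coefficient of variation `noise_cv`; bins whose
#' centers lie within `center_halfwidth` of a site midpoint have their
#' mean multiplied by `center_fold` (additionally by
#' `orientation_bias` at head-on sites).
#'
#' @param sites site intervals (uses `orientation` column when
#'   present).
#' @param spec factor spec list (see [make_factor_specs()]).
#' @param chrom_lengths named chromosome lengths.
#' @param binsize bin width (bp).
#' @param seed RNG seed.
#' @param center_halfwidth planted-effect half-width (default 10000).
#' @return a [signal_track()] of non-negative values.
#' @export
simulate_factor_track <- function(sites, spec, chrom_lengths, binsize,
                                  seed, center_halfwidth = 10000) {
  if (spec$center_fold <= 0) stop("center_fold must be > 0")
  set.seed(seed)
  cv <- spec$noise_cv %||% 0
  sdlog <- sqrt(log(1 + cv^2))
  bias <- spec$orientation_bias %||% 1
  vals <- lapply(names(chrom_lengths), function(ch) {
    nb <- as.integer(ceiling(chrom_lengths[[ch]] / binsize))
    centers <- (seq_len(nb) - 0.5) * binsize
    level <- rep(spec$flank_level, nb)
    si <- which(sites$chrom == ch)
    if (length(si)) {
      mids <- interval_midpoints(sites[si, , drop = FALSE])
      orient <- if ("orientation" %in% names(sites)) {
        sites$orientation[si]
      } else {
        rep("codirectional", length(si))
      }
      for (k in seq_along(si)) {
        fold <- spec$center_fold *
          if (orient[k] == "head_on") bias else 1
        hit <- abs(centers - mids[k]) <= center_halfwidth
        level[hit] <- level[hit] * fold
      }
    }
    noise <- if (cv > 0) {
      exp(stats::rnorm(nb, -sdlog^2 / 2, sdlog))
    } else {
      rep(1, nb)
    }
    level * noise
  })
  names(vals) <- names(chrom_lengths)
  signal_track(vals, binsize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regularly spaced synthetic TRC sites
#'
#' Builds a frame of equal-width sites at fixed spacing on one
#' chromosome with alternating strand and fork direction (so head-on
#' and co-directional orientations alternate deterministically).
#' Useful for quantitative recovery tests where planted center effects
#' of neighbouring sites must not contaminate each other's flanks.
#'
#' @param n number of sites.
#' @param spacing center-to-center distance in bp.
#' @param width site width in bp.
#' @param chrom chromosome name.
#' @param offset position of the first site start (bp).
#' @return TRC-style site data.frame with `fork_direction` and
#'   `orientation` columns; attribute `chrom_length` gives the minimal
#'   chromosome length accommodating the layout plus `offset` of
#'   margin.
#' @export
make_trc_sites <- function(n, spacing = 150000, width = 1000,
                           chrom = "chrS", offset = 1.05e6) {
  start <- offset + (seq_len(n) - 1) * spacing
  strand <- rep(c("+", "-"), length.out = n)
  fork <- rep(c("rightward", "rightward", "leftward", "leftward"),
              length.out = n)
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   name = sprintf("site_%d", seq_len(n)), score = 0,
                   strand = strand, stringsAsFactors = FALSE)
  df$mean_rfd <- ifelse(fork == "rightward", 1, -1)
  df$fork_direction <- fork
  df$orientation <- ifelse((fork == "rightward" & strand == "-") |
                             (fork == "leftward" & strand == "+"),
                           "head_on", "codirectional")
  attr(df, "chrom_length") <- max(df$end) + offset
  df
}

## ---- genome context engine -------------------------------------------

# integer base codes A=1 C=2 G=3 T=4; pyrimidine collapse C/G -> "C",
# A/T -> "T"
.base_codes <- local({
  m <- integer(128)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m
})

.pyr_trinucs <- local({
  b <- c("A", "C", "G", "T")
  out <- character(0)
  for (c0 in c("C", "T")) for (l in b) for (r in b) {
    out <- c(out, paste0(l, c0, r))
  }
  sort(out)
})

# map code64 (0-based: 16*(l-1)+4*(c-1)+(r-1)) -> index into .pyr_trinucs
.ctx_map64 <- local({
  b <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- integer(64)
  for (l in 1:4) for (c0 in 1:4) for (r in 1:4) {
    code <- 16 * (l - 1) + 4 * (c0 - 1) + (r - 1) + 1
    tri <- paste0(b[l], b[c0], b[r])
    if (b[c0] %in% c("A", "G")) {
      tri <- paste0(comp[b[r]], comp[b[c0]], comp[b[l]])
    }
    out[code] <- match(tri, .pyr_trinucs)
  }
  out
})

# global position arrays over a concatenated genome
.context_engine <- function(genome) {
  lens <- nchar(genome)
  offsets <- cumsum(c(0, lens[-length(lens)]))
  names(offsets) <- names(genome)
  total <- sum(lens)
  base <- integer(total)
  for (i in seq_along(genome)) {
    base[offsets[i] + seq_len(lens[i])] <-
      .base_codes[utf8ToInt(genome[[i]])]
  }
  ctx <- rep(NA_integer_, total)
  for (i in seq_along(genome)) {
    if (lens[i] < 3) next
    idx <- offsets[i] + 2:(lens[i] - 1)
    code <- 16L * (base[idx - 1] - 1L) + 4L * (base[idx] - 1L) +
      (base[idx + 1] - 1L) + 1L
    ctx[idx] <- .ctx_map64[code]
  }
  # homopolymer runs (per chromosome, so runs never span chromosomes)
  runlen <- integer(total)
  runstart <- integer(total)
  for (i in seq_along(genome)) {
    idx <- offsets[i] + seq_len(lens[i])
    r <- rle(base[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runlen[idx] <- rep(r$lengths, r$lengths)
    runstart[idx] <- offsets[i] + rep(starts, r$lengths)
  }
  pyr <- c("T", "C", "C", "T")[base]
  list(offsets = offsets, lens = lens, total = total, base = base,
       ctx = ctx, runlen = runlen, runstart = runstart, pyr = pyr,
       chrom_starts = unname(offsets) + 1L, chroms = names(genome))
}

.global_to_local <- function(eng, g) {
  i <- findInterval(g, eng$offsets + 1)
  list(chrom = eng$chroms[i], pos = g - eng$offsets[i])
}

.intervals_to_global <- function(eng, intervals) {
  if (nrow(intervals) == 0) return(integer(0))
  unlist(lapply(seq_len(nrow(intervals)), function(k) {
    off <- eng$offsets[[intervals$chrom[k]]]
    # 0-based half-open [start, end) -> 1-based global positions
    off + (intervals$start[k] + 1):intervals$end[k]
  }), use.names = FALSE)
}

## ---- mutation simulation ---------------------------------------------

# parse signature channel rownames into placement descriptors
.parse_channels <- function(labels) {
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", lab)) {
      tri <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
      out[[i]] <- list(kind = "SBS", ctx = match(tri, .pyr_trinucs),
                       alt = substr(lab, 5, 5))
    } else if (grepl("^1:(Del|Ins):[CT]:[0-5]$", lab)) {
      p <- strsplit(lab, ":", fixed = TRUE)[[1]]
      out[[i]] <- list(kind = p[2], base = p[3], sub = as.integer(p[4]))
    } else {
      stop(sprintf(
        "unsupported generator channel '%s' (SBS96 or 1-bp ID83 labels only)",
        lab))
    }
  }
  names(out) <- labels
  out
}

# predicate over global positions for a placement descriptor
.channel_predicate <- function(eng, desc) {
  switch(desc$kind,
    SBS = function(g) !is.na(eng$ctx[g]) & eng$ctx[g] == desc$ctx,
    Del = function(g) {
      # anchor (runstart - 1) must exist on the same chromosome
      eng$pyr[g] == desc$base &
        pmin(eng$runlen[g] - 1L, 5L) == desc$sub &
        !(eng$runstart[g] %in% eng$chrom_starts)
    },
    Ins = function(g) {
      # g is the anchor; the run (or empty context) starts at g+1
      nxt <- pmin(g + 1L, eng$total)
      same_chrom <- g + 1L <= eng$total & !(g + 1L) %in% eng$chrom_starts
      if (desc$sub == 0) {
        bc <- if (desc$base == "C") 2L else 4L  # exact inserted base
        same_chrom & eng$base[g] != bc & eng$base[nxt] != bc
      } else {
        same_chrom & eng$pyr[nxt] == desc$base &
          eng$base[g] != eng$base[nxt] &
          pmin(eng$runlen[nxt], 5L) == desc$sub
      }
    })
}

# draw n positions satisfying pred: from a class pool (sampled with
# replacement) or by rejection from the whole genome avoiding in_site
.draw_positions <- function(eng, pred, n, pool = NULL, avoid = NULL,
                            max_rounds = 60) {
  if (n == 0) return(integer(0))
  if (!is.null(pool)) {
    ok <- pool[pred(pool)]
    if (!length(ok)) return(NULL)
    return(ok[sample.int(length(ok), n, replace = TRUE)])
  }
  out <- integer(0)
  for (round in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0) break
    cand <- sample.int(eng$total, max(1000L, need * 40L), replace = TRUE)
    keep <- pred(cand)
    if (!is.null(avoid)) keep <- keep & !avoid[cand]
    cand <- cand[keep]
    out <- c(out, cand[seq_len(min(length(cand), need))])
  }
  if (length(out) < n) return(NULL)
  out
}

#' Simulate tumor mutation catalogs with planted regional effects
#'
#' Per tumor, a fixed number of mutations is drawn: each mutation's
#' signature comes from the tumor's mixture, its channel from that
#' signature's channel distribution, and its position from a region
#' class chosen with probability proportional to class length times
#' planted rate multipliers (head-on TRC sites carry
#' `ho_rate_multiplier`; all R-loop sites carry `burden_multiplier`
#' in remodeler-deficient tumors), uniformly among positions whose
#' reference context matches the channel. Deficient tumors additionally
#' receive one disrupting (frameshift/missense/nonsense) mutation in
#' the target gene, placed before burden sampling.
#'
#' @param config a [simulation_config()] with `signature_defs` and
#'   `tumor_specs`.
#' @param genome named character vector of reference sequences.
#' @param rloop_sites R-loop peak intervals.
#' @param trcs TRC site data.frame with `orientation` (truth or called).
#' @param genes gene intervals (for functional annotation and the
#'   deficiency target).
#' @return list: `mutations` (mutation data.frame), `truth`
#'   (per-mutation `signature` and `region_class`), `tumor_truth`
#'   (per-tumor planted status).
#' @export
simulate_mutations <- function(config, genome, rloop_sites, trcs, genes) {
  ts <- config$tumor_specs
  n_tumors <- ts$n_tumors %||% 0
  if (n_tumors == 0) {
    stop("tumor_specs$n_tumors must be >= 1 to simulate mutations")
  }
  sig_defs <- as.matrix(config$signature_defs)
  if (is.null(rownames(sig_defs))) stop("signature_defs needs channel rownames")
  k <- ncol(sig_defs)
  if (is.null(colnames(sig_defs))) {
    colnames(sig_defs) <- sprintf("sig%d", seq_len(k))
  }
  n_mut <- ts$mutations_per_tumor %||% 1000
  mix <- ts$signature_mixture %||% rep(1 / k, k)
  if (!is.matrix(mix)) {
    # per-tumor exposures vary around the base mixture (Dirichlet);
    # without between-tumor variability the count matrix is rank 1 and
    # no factorization could separate the signatures
    conc <- ts$mixture_concentration %||% 0.7
    alpha <- mix * k * conc
    g <- matrix(stats::rgamma(k * n_tumors, shape = alpha), k, n_tumors)
    mix <- sweep(g, 2, colSums(g), "/")
  }
  # scalar: all signatures up-weighted at head-on sites; vector: one
  # multiplier per signature (plants signature-specific HO activity)
  ho_mult <- rep_len(as.numeric(ts$ho_rate_multiplier %||% 1), k)
  defic_frac <- ts$deficient_fraction %||% 0
  burden_mult <- ts$burden_multiplier %||% 1
  target_gene <- ts$target_gene %||% genes$name[1]
  eng <- .context_engine(genome)
  descs <- .parse_channels(rownames(sig_defs))

  ho <- trcs[trcs$orientation == "head_on", , drop = FALSE]
  cd <- trcs[trcs$orientation == "codirectional", , drop = FALSE]
  in_trc <- paste(rloop_sites$chrom, rloop_sites$start) %in%
    paste(trcs$chrom, trcs$start)
  other <- rloop_sites[!in_trc, , drop = FALSE]
  class_frames <- list(ho = ho, cd = cd, rloop = other)
  pools <- lapply(class_frames, function(fr) .intervals_to_global(eng, fr))
  in_site <- logical(eng$total)
  in_site[unlist(pools, use.names = FALSE)] <- TRUE
  class_bp <- vapply(pools, length, numeric(1))
  bg_bp <- eng$total - sum(class_bp)

  tumors <- sprintf("tumor_%d", seq_len(n_tumors))
  n_def <- round(defic_frac * n_tumors)
  deficient <- c(rep(TRUE, n_def), rep(FALSE, n_tumors - n_def))

  # per-mutation frame, tumor-major order
  sig_idx <- integer(0); tum_idx <- integer(0)
  for (t in seq_len(n_tumors)) {
    sig_idx <- c(sig_idx, sample.int(k, n_mut, replace = TRUE,
                                     prob = mix[, t]))
    tum_idx <- c(tum_idx, rep(t, n_mut))
  }
  n_all <- length(sig_idx)
  chan_idx <- integer(n_all)
  for (s in seq_len(k)) {
    rows <- which(sig_idx == s)
    if (length(rows)) {
      chan_idx[rows] <- sample.int(nrow(sig_defs), length(rows),
                                   replace = TRUE, prob = sig_defs[, s])
    }
  }
  # region class per mutation: weights depend on tumor deficiency and
  # on the mutation's generating signature (HO multiplier)
  class_of <- character(n_all)
  for (def in c(TRUE, FALSE)) {
    for (s in seq_len(k)) {
      rows <- which(deficient[tum_idx] == def & sig_idx == s)
      if (!length(rows)) next
      b <- if (def) burden_mult else 1
      w <- c(ho = class_bp[["ho"]] * b * ho_mult[s],
             cd = class_bp[["cd"]] * b,
             rloop = class_bp[["rloop"]] * b,
             background = bg_bp)
      class_of[rows] <- sample(names(w), length(rows), replace = TRUE,
                               prob = w / sum(w))
    }
  }
  # positions per (class, channel-context group)
  gpos <- integer(n_all)
  short <- 0
  for (cl in unique(class_of)) {
    for (ci in unique(chan_idx[class_of == cl])) {
      rows <- which(class_of == cl & chan_idx == ci)
      pred <- .channel_predicate(eng, descs[[ci]])
      drawn <- if (cl == "background") {
        .draw_positions(eng, pred, length(rows), avoid = in_site)
      } else {
        .draw_positions(eng, pred, length(rows), pool = pools[[cl]])
      }
      if (is.null(drawn)) {
        # context unavailable in that class: fall back to background
        drawn <- .draw_positions(eng, pred, length(rows), avoid = in_site)
        short <- short + length(rows)
        if (is.null(drawn)) {
          stop(sprintf("context for channel '%s' absent from genome",
                       names(descs)[ci]))
        }
      }
      gpos[rows] <- drawn
    }
  }
  if (short > 0) {
    warning(sprintf(
      "%d mutation(s) re-placed in the background: context absent in target class",
      short))
  }

  b4 <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  kind_of <- vapply(descs, function(d) d$kind, character(1))[chan_idx]
  ref <- character(n_all); alt <- character(n_all)
  mclass <- character(n_all)
  is_snv <- kind_of == "SBS"
  if (any(is_snv)) {
    g <- gpos[is_snv]
    r <- b4[eng$base[g]]
    lab_alt <- vapply(descs, function(d) d$alt %||% "", character(1))
    a <- lab_alt[chan_idx[is_snv]]
    pur <- r %in% c("A", "G")
    a[pur] <- unname(comp[a[pur]])
    ref[is_snv] <- r; alt[is_snv] <- a; mclass[is_snv] <- "SNV"
  }
  is_del <- kind_of == "Del"
  if (any(is_del)) {
    q <- eng$runstart[gpos[is_del]]  # emit left-aligned at the run start
    anchor <- q - 1L
    ref[is_del] <- paste0(b4[eng$base[anchor]], b4[eng$base[q]])
    alt[is_del] <- b4[eng$base[anchor]]
    gpos[is_del] <- anchor
    mclass[is_del] <- "DEL"
  }
  is_ins <- kind_of == "Ins"
  if (any(is_ins)) {
    g <- gpos[is_ins]
    sub0 <- vapply(descs, function(d) (d$sub %||% -1L) == 0, logical(1))
    base_lab <- vapply(descs, function(d) d$base %||% "", character(1))
    ins <- ifelse(sub0[chan_idx[is_ins]], base_lab[chan_idx[is_ins]],
                  b4[eng$base[pmin(g + 1L, eng$total)]])
    ref[is_ins] <- b4[eng$base[g]]
    alt[is_ins] <- paste0(ref[is_ins], ins)
    mclass[is_ins] <- "INS"
  }
  loc <- .global_to_local(eng, gpos)
  pos <- loc$pos
  gi <- point_interval_index(loc$chrom, pos - 1, genes)
  func <- ifelse(is.na(gi), "noncoding", "synonymous")
  mut <- data.frame(sample = tumors[tum_idx], chrom = loc$chrom, pos = pos,
                    start = pos - 1, ref = ref, alt = alt,
                    mut_class = mclass, functional_class = func,
                    gene = ifelse(is.na(gi), NA_character_, genes$name[gi]),
                    stringsAsFactors = FALSE)
  truth <- data.frame(sample = tumors[tum_idx],
                      signature = colnames(sig_defs)[sig_idx],
                      region_class = class_of, stringsAsFactors = FALSE)
  # planted disrupting mutations in the target gene for deficient tumors
  if (n_def > 0) {
    tg <- genes[genes$name == target_gene, , drop = FALSE]
    if (nrow(tg) != 1) stop(sprintf("target gene '%s' not found", target_gene))
    dpos <- tg$start[1] + 1 + floor(stats::runif(n_def) *
                                      (tg$end[1] - tg$start[1]))
    dref <- substr(rep(genome[[tg$chrom[1]]], n_def), dpos, dpos)
    dalt <- vapply(dref, function(r) sample(setdiff(b4, r), 1), character(1))
    dfun <- sample(c("frameshift", "missense", "nonsense"), n_def,
                   replace = TRUE)
    dmut <- data.frame(sample = tumors[seq_len(n_def)], chrom = tg$chrom[1],
                       pos = dpos, start = dpos - 1, ref = unname(dref),
                       alt = unname(dalt), mut_class = "SNV",
                       functional_class = dfun, gene = target_gene,
                       stringsAsFactors = FALSE)
    dtruth <- data.frame(sample = dmut$sample, signature = "planted_disruption",
                         region_class = "target_gene",
                         stringsAsFactors = FALSE)
    mut <- rbind(dmut, mut)
    truth <- rbind(dtruth, truth)
  }
  ord <- order(match(mut$sample, tumors), mut$chrom, mut$pos)
  mut <- mut[ord, , drop = FALSE]; truth <- truth[ord, , drop = FALSE]
  rownames(mut) <- rownames(truth) <- NULL
  list(mutations = mut, truth = truth,
       tumor_truth = data.frame(sample = tumors,
                                status = ifelse(deficient, "deficient",
                                                "proficient"),
                                stringsAsFactors = FALSE))
}

#' Simulate a chromatin contact map with planted upstream compaction
#'
#' Background contacts decay as `(|i - j| + 1)^(-alpha)`; all entries
#' involving bins 0.2-1 Mb upstream (fork-wise) of a head-on TRC site
#' are multiplied by `upstream_compaction_fold`. The map is symmetric.
#'
#' @param config a [simulation_config()] (uses `contact_spec`).
#' @param trcs TRC site data.frame with `fork_direction` and
#'   `orientation`.
#' @param chrom_lengths named chromosome lengths.
#' @return a [contact_map()].
#' @export
simulate_contacts <- function(config, trcs, chrom_lengths) {
  cs <- config$contact_spec
  alpha <- cs$alpha %||% 1
  if (alpha <= 0) stop("contact decay exponent alpha must be > 0")
  bs <- cs$binsize %||% 10000
  fold <- cs$upstream_compaction_fold %||% 1
  mats <- lapply(names(chrom_lengths), function(ch) {
    n <- as.integer(ceiling(chrom_lengths[[ch]] / bs))
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    m <- (d + 1)^(-alpha)
    si <- which(trcs$chrom == ch & trcs$orientation == "head_on")
    if (length(si) && fold != 1) {
      mids <- interval_midpoints(trcs[si, , drop = FALSE])
      right <- trcs$fork_direction[si] == "rightward"
      lo <- ifelse(right, mids - 1e6, mids + 2e5)
      hi <- ifelse(right, mids - 2e5, mids + 1e6)
      # compaction is local: contacts among the upstream bins of each
      # head-on site are scaled, leaving the rest of the map untouched
      mult <- matrix(1, n, n)
      for (j in seq_along(si)) {
        b0 <- max(1, floor(lo[j] / bs) + 1)
        b1 <- min(n, ceiling(hi[j] / bs))
        if (b0 <= b1) mult[b0:b1, b0:b1] <- fold
      }
      m <- m * mult
    }
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
  names(mats) <- names(chrom_lengths)
  contact_map(mats, bs)
}

## ---- full bundle ------------------------------------------------------

#' Generate the complete synthetic bundle
#'
#' Runs every generator under the master seed, writes the on-disk
#' bundle (FASTA, gene BED with expression scores, stranded R-loop
#' BED6, RFD bedGraph, per-factor bedGraphs, mutation TSV, contact
#' triplets, truth tables) and returns the in-memory objects alongside
#' the paths. Identical configurations produce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created); `NULL` keeps everything
#'   in memory only.
#' @return list of class `synthetic_bundle`: `config`, `genome`,
#'   `genes`, `rloops`, `rfd` (track), `origins`, `factor_tracks`,
#'   `mutations`, `contacts`, truth tables (`site_truth`,
#'   `factor_truth`, `tumor_truth`, `mutation_truth`) and `paths`.
#' @export
simulate_genome <- function(config, outdir = NULL) {
  config <- validate_simulation_config(config)
  set.seed(config$seed)
  cl <- config$chrom_lengths
  chroms <- names(cl)

  ## genes: allocate by chromosome length into non-overlapping slots
  alloc <- if (config$n_genes > 0) {
    a <- floor(config$n_genes * cl / sum(cl))
    rem <- config$n_genes - sum(a)
    if (rem > 0) a[seq_len(rem)] <- a[seq_len(rem)] + 1
    a
  } else {
    stats::setNames(rep(0, length(cl)), chroms)
  }
  genes <- list()
  gid <- 0
  for (ch in chroms) {
    ng <- alloc[[ch]]
    if (ng == 0) next
    span <- cl[[ch]] - 2 * config$edge_margin
    slot <- span / ng
    if (span <= 0 || slot < 300) {
      stop(sprintf("infeasible config: %d genes do not fit on %s", ng, ch))
    }
    len <- pmin(stats::rlnorm(ng, config$gene_length_meanlog,
                              config$gene_length_sdlog),
                0.8 * slot)
    len <- pmax(round(len), 200)
    start <- config$edge_margin + (seq_len(ng) - 1) * slot +
      floor(stats::runif(ng) * (slot - len))
    start <- round(start)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    silenced <- stats::runif(ng) < config$silenced_fraction
    expr <- ifelse(silenced, 0,
                   stats::rlnorm(ng, config$expression_meanlog,
                                 config$expression_sdlog))
    genes[[ch]] <- data.frame(chrom = ch, start = start, end = start + len,
                              name = sprintf("gene_%d", gid + seq_len(ng)),
                              score = expr, strand = strand,
                              stringsAsFactors = FALSE)
    gid <- gid + ng
  }
  genes <- if (length(genes)) {
    do.call(rbind, genes)
  } else {
    genomic_intervals(character(0), numeric(0), numeric(0))
  }
  rownames(genes) <- NULL
  genes$expression <- genes$score

  ## sequence: i.i.d. with a per-gene GC knob
  genome <- vapply(chroms, function(ch) {
    L <- cl[[ch]]
    gc <- rep(config$gc_background, L)
    gi <- which(genes$chrom == ch)
    for (g in gi) gc[(genes$start[g] + 1):genes$end[g]] <- config$gc_gene
    is_gc <- stats::runif(L) < gc
    strong <- sample(c("G", "C"), L, replace = TRUE)
    weak <- sample(c("A", "T"), L, replace = TRUE)
    paste(ifelse(is_gc, strong, weak), collapse = "")
  }, character(1))

  ## replication origins and RFD
  origins <- lapply(chroms, function(ch) {
    gaps <- stats::rexp(ceiling(cl[[ch]] / config$origin_spacing) * 3,
                        rate = 1 / config$origin_spacing)
    o <- cumsum(gaps)
    o[o < cl[[ch]]]
  })
  names(origins) <- chroms
  rfd_vals <- lapply(chroms, function(ch) {
    simulate_rfd(origins[[ch]], cl[[ch]], config$rfd_binsize,
                 config$terminus_width)
  })
  names(rfd_vals) <- chroms
  rfd <- signal_track(rfd_vals, config$rfd_binsize, rfd = TRUE)

  ## R-loop peaks at expressed genes
  p_rloop <- config$rloop_max * genes$expression /
    (genes$expression + config$rloop_halfsat)
  p_rloop[genes$expression == 0] <- 0
  has_peak <- stats::runif(nrow(genes)) < p_rloop
  widths <- round(stats::rlnorm(nrow(genes), config$rloop_width_meanlog,
                                config$rloop_width_sdlog))
  rl <- genes[has_peak, , drop = FALSE]
  w <- pmin(widths[has_peak], rl$end - rl$start)
  w <- pmax(w, 100)
  off <- floor(stats::runif(nrow(rl)) * (rl$end - rl$start - w + 1))
  rloops <- data.frame(chrom = rl$chrom, start = rl$start + off,
                       end = rl$start + off + w,
                       name = sprintf("rloop_%s", rl$name),
                       score = rl$expression, strand = rl$strand,
                       stringsAsFactors = FALSE)
  rloops <- validate_intervals(rloops, what = "R-loop peak")

  ## truth orientation from the analytic RFD model (per-bp mean)
  site_truth <- rloops
  site_truth$planted_rfd <- vapply(seq_len(nrow(rloops)), function(i) {
    ch <- rloops$chrom[i]
    mean(.rfd_at(rloops$start[i]:(rloops$end[i] - 1) + 0.5, origins[[ch]],
                 config$terminus_width))
  }, numeric(1))
  site_truth$fork_direction <- ifelse(site_truth$planted_rfd > 0,
                                      "rightward", "leftward")
  site_truth$orientation <- ifelse(
    (site_truth$planted_rfd > 0 & site_truth$strand == "-") |
      (site_truth$planted_rfd < 0 & site_truth$strand == "+"),
    "head_on", "codirectional")
  site_truth$is_trc <- abs(site_truth$planted_rfd) > config$trc_threshold
  truth_trcs <- site_truth[site_truth$is_trc, , drop = FALSE]

  ## factor tracks with planted center effects at true TRC sites
  factor_tracks <- list()
  factor_truth <- NULL
  if (length(config$factor_specs)) {
    fseeds <- sample.int(.Machine$integer.max - 1, length(config$factor_specs))
    factor_tracks <- lapply(seq_along(config$factor_specs), function(i) {
      simulate_factor_track(truth_trcs, config$factor_specs[[i]], cl,
                            config$factor_binsize, seed = fseeds[i])
    })
    names(factor_tracks) <- names(config$factor_specs)
    factor_truth <- data.frame(
      factor = names(config$factor_specs),
      planted_class = vapply(config$factor_specs, function(s) {
        s$planted_class %||%
          if (s$center_fold > 1) "enriched" else
            if (s$center_fold < 1) "depleted" else "none"
      }, character(1)),
      center_fold = vapply(config$factor_specs, function(s) s$center_fold,
                           numeric(1)),
      stringsAsFactors = FALSE)
    set.seed(config$seed + 1L)  # restore a deterministic stream position
  }

  ## tumors and mutations
  mutations <- NULL; mutation_truth <- NULL; tumor_truth <- NULL
  if ((config$tumor_specs$n_tumors %||% 0) > 0) {
    sim <- simulate_mutations(config, genome, rloops, truth_trcs, genes)
    mutations <- sim$mutations
    mutation_truth <- sim$truth
    tumor_truth <- sim$tumor_truth
  }

  ## contacts
  contacts <- simulate_contacts(config, truth_trcs, cl)

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(outdir, "genome.fa"),
      genes = file.path(outdir, "genes.bed"),
      rloops = file.path(outdir, "rloops.bed"),
      rfd = file.path(outdir, "rfd.bedGraph"),
      mutations = file.path(outdir, "mutations.tsv"),
      contacts = file.path(outdir, "contacts.tsv"),
      site_truth = file.path(outdir, "truth_sites.tsv"),
      factor_truth = file.path(outdir, "truth_factors.tsv"),
      tumor_truth = file.path(outdir, "truth_tumors.tsv"),
      mutation_truth = file.path(outdir, "truth_mutations.tsv"),
      factors = stats::setNames(
        file.path(outdir, sprintf("factor_%s.bedGraph",
                                  names(factor_tracks))),
        names(factor_tracks)))
    write_sequence(genome, paths$fasta)
    write_intervals(genes, paths$genes)
    write_intervals(rloops, paths$rloops)
    write_signal(rfd, paths$rfd)
    for (nm in names(factor_tracks)) {
      write_signal(factor_tracks[[nm]], paths$factors[[nm]])
    }
    if (!is.null(mutations)) write_mutations(mutations, paths$mutations)
    write_contacts(contacts, paths$contacts)
    wt <- function(df, p) {
      if (!is.null(df)) {
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    wt(site_truth, paths$site_truth)
    wt(factor_truth, paths$factor_truth)
    wt(tumor_truth, paths$tumor_truth)
    wt(mutation_truth, paths$mutation_truth)
  }

  structure(list(config = config, genome = genome, genes = genes,
                 rloops = rloops, rfd = rfd, origins = origins,
                 factor_tracks = factor_tracks, mutations = mutations,
                 contacts = contacts, site_truth = site_truth,
                 factor_truth = factor_truth, tumor_truth = tumor_truth,
                 mutation_truth = mutation_truth, paths = paths),
            class = "synthetic_bundle")
}

#' @method print synthetic_bundle
#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic_bundle: %d chromosome(s) (%.1f Mb), %d genes, %d R-loop peaks\n",
    length(x$genome), sum(nchar(x$genome)) / 1e6, nrow(x$genes),
    nrow(x$rloops)))
  cat(sprintf("  %d true TRC sites (%d head-on / %d co-directional)\n",
              sum(x$site_truth$is_trc),
              sum(x$site_truth$is_trc & x$site_truth$orientation == "head_on"),
              sum(x$site_truth$is_trc &
                    x$site_truth$orientation == "codirectional")))
  if (!is.null(x$mutations)) {
    cat(sprintf("  %d mutations in %d tumors\n", nrow(x$mutations),
                length(unique(x$mutations$sample))))
  }
  cat(sprintf("  %d factor track(s), seed %d\n", length(x$factor_tracks),
              x$config$seed))
  invisible(x)
}
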