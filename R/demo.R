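#' Default run configuration
#'
#' Namespaced parameter blocks for every pipeline stage, plus the
#' global seed. `validate_config()` fills these defaults from a flat
#' key/value file.
#'
#' @return list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    trc = trc_params(),
    screen = screen_params(),
    hotspot = hotspot_params(),
    burden = burden_params(),
    signature = signature_params()
  ), class = "run_config")
}

# flat key -> (block, field) spec with coercers
.config_keys <- list(
  seed = list(NULL, "seed", as.integer),
  `trc.rfd_threshold` = list("trc", "rfd_threshold", as.numeric),
  `trc.min_covered_fraction` = list("trc", "min_covered_fraction", as.numeric),
  `trc.strict` = list("trc", "strict", function(x) as.logical(toupper(x))),
  `screen.center_halfwidth` = list("screen", "center_halfwidth", as.numeric),
  `screen.flank_width` = list("screen", "flank_width", as.numeric),
  `screen.flank_offset` = list("screen", "flank_offset", as.numeric),
  `screen.window_halfwidth` = list("screen", "window_halfwidth", as.numeric),
  `screen.rms_cutoff` = list("screen", "rms_cutoff", as.numeric),
  `screen.orient_by` = list("screen", "orient_by", as.character),
  `screen.stat` = list("screen", "stat", as.character),
  `hotspot.binsize` = list("hotspot", "binsize", as.numeric),
  `hotspot.c_peak` = list("hotspot", "c_peak", as.numeric),
  `hotspot.c_link` = list("hotspot", "c_link", as.numeric),
  `hotspot.min_len` = list("hotspot", "min_len", as.numeric),
  `hotspot.max_gap` = list("hotspot", "max_gap", as.numeric),
  `burden.min_mutations` = list("burden", "min_mutations", as.numeric),
  `burden.normalize` = list("burden", "normalize", as.character),
  `signature.n_restarts` = list("signature", "n_restarts", as.integer),
  `signature.max_iter` = list("signature", "max_iter", as.integer),
  `signature.tol` = list("signature", "tol", as.numeric),
  `signature.seed` = list("signature", "seed", as.integer),
  `signature.pseudocount` = list("signature", "pseudocount", as.numeric)
)

#' Validate and normalize a run configuration
#'
#' Reads a flat `key = value` text file with namespaced keys (for
#' example `screen.rms_cutoff = 0.3`), fills defaults for everything
#' unset, rejects unknown keys, and re-runs every block constructor so
#' all invariants are enforced. Passing an existing `run_config`
#' normalizes it idempotently.
#'
#' @param path config file path, or a `run_config` list.
#' @return normalized `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- default_run_config()
  if (inherits(path, "run_config") || is.list(path)) {
    overrides <- list()
    src <- path
    cfg$seed <- as.integer(src$seed %||% cfg$seed)
    for (blk in c("trc", "screen", "hotspot", "burden", "signature")) {
      if (!is.null(src[[blk]])) cfg[[blk]] <- src[[blk]]
    }
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop(sprintf("malformed config line '%s' (expected key = value)", ln))
      }
      key <- trimws(kv[1]); val <- trimws(kv[2])
      spec <- .config_keys[[key]]
      if (is.null(spec)) stop(sprintf("unknown config key '%s'", key))
      coerced <- suppressWarnings(spec[[3]](val))
      if (length(coerced) != 1 || is.na(coerced)) {
        stop(sprintf("type mismatch for config key '%s': '%s'", key, val))
      }
      if (is.null(spec[[1]])) {
        cfg[[spec[[2]]]] <- coerced
      } else {
        cfg[[spec[[1]]]][[spec[[2]]]] <- coerced
      }
    }
  }
  # re-run constructors so invariants are checked with key names intact
  cfg$trc <- do.call(trc_params, unclass(cfg$trc))
  cfg$screen <- do.call(screen_params, unclass(cfg$screen))
  cfg$hotspot <- do.call(hotspot_params, unclass(cfg$hotspot))
  cfg$burden <- do.call(burden_params, unclass(cfg$burden))
  cfg$signature <- do.call(signature_params, unclass(cfg$signature))
  class(cfg) <- "run_config"
  cfg
}

# demo-scale synthetic study conditions: small genome, reduced flank
# offsets, planted effects on every axis the pipeline measures
.demo_sim_config <- function(seed) {
  sigs <- .demo_signatures()
  simulation_config(
    seed = seed,
    chrom_lengths = c(chrA = 3e6, chrB = 3e6),
    n_genes = 120,
    origin_spacing = 120000,
    terminus_width = 24000,
    edge_margin = 1.05e6,
    factor_specs = c(
      make_factor_specs(3, center_fold = 1.5, noise_cv = 0.1,
                        prefix = "enriched"),
      make_factor_specs(1, center_fold = 0.6, noise_cv = 0.1,
                        prefix = "depleted"),
      make_factor_specs(2, center_fold = 1, noise_cv = 0.1,
                        prefix = "null")),
    signature_defs = sigs,
    tumor_specs = list(n_tumors = 24, mutations_per_tumor = 800,
                       signature_mixture = c(0.12, 0.44, 0.44),
                       ho_rate_multiplier = c(4, 2, 2),
                       deficient_fraction = 0.5,
                       burden_multiplier = 2, target_gene = "gene_1"),
    contact_spec = list(binsize = 10000, alpha = 1,
                        upstream_compaction_fold = 2))
}

# well-separated peaked SBS signatures on disjoint channel blocks
# (a handful of dominant channels each, like real peaked signatures),
# plus a 1-bp indel tail on each
.demo_signatures <- function(k = 3, indel_weight = 0.06, per_block = 5) {
  labs <- sbs96_labels()
  id_labs <- c("1:Del:C:0", "1:Del:T:1", "1:Ins:C:0", "1:Ins:T:1")
  all_labs <- c(labs, id_labs)
  W <- matrix(0, length(all_labs), k,
              dimnames = list(all_labs, sprintf("sig%d", seq_len(k))))
  block <- split(seq_along(labs), cut(seq_along(labs), k, labels = FALSE))
  for (s in seq_len(k)) {
    act <- block[[s]][seq_len(min(per_block, length(block[[s]])))]
    W[act, s] <- (1 - indel_weight) / length(act)
    W[id_labs[(s %% length(id_labs)) + 1], s] <- indel_weight
  }
  W
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the synthetic end-to-end demonstration pipeline
#'
#' Simulates a seeded synthetic bundle, then runs every stage —
#' TRC calling, the factor screen, orientation comparison, hotspot
#' calling and gene association, per-site mutation rates, the R-loop
#' burden contrast, SBS96 signature extraction/refit/assignment,
#' region risk ratios, factor-signature clustering and contact
#' aggregation — and writes a human-readable report plus a
#' machine-readable metrics JSON. Identical seeds give byte-identical
#' metrics files.
#'
#' @param outdir writable output directory.
#' @param seed integer seed driving every stochastic stage.
#' @param config optional `run_config` (see [validate_config()]);
#'   demo-scale analysis windows are used where the defaults target
#'   full-genome scale.
#' @return (invisibly) the metrics list; files `report.txt` and
#'   `metrics.json` under `outdir`.
#' @export
run_demo <- function(outdir, seed = 1, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (is.null(config)) default_run_config() else validate_config(config)
  cfg$seed <- as.integer(seed)
  # demo-scale windows: the synthetic genome is 2 x 2 Mb
  cfg$screen$flank_offset <- min(cfg$screen$flank_offset, 3e5)
  cfg$screen$window_halfwidth <- min(cfg$screen$window_halfwidth, 3e5)
  cfg$burden$min_mutations <- min(cfg$burden$min_mutations, 500)

  sim_cfg <- .demo_sim_config(seed)
  bundle <- .stage("simulate", simulate_genome(sim_cfg,
                                               file.path(outdir, "bundle")))
  trcs <- .stage("call-trcs", call_trcs(bundle$rloops, bundle$rfd, cfg$trc))
  screen <- .stage("screen",
                   screen_factors(trcs, bundle$factor_tracks, cfg$screen))
  orient <- .stage("orientation", {
    ho_biased <- simulate_factor_track(
      trcs, list(center_fold = 2, flank_level = 1, noise_cv = 0.1,
                 orientation_bias = 2),
      sim_cfg$chrom_lengths, sim_cfg$factor_binsize, seed = seed + 7)
    compare_orientations(trcs, ho_biased, cfg$screen)
  })
  muts <- bundle$mutations
  hot <- .stage("hotspots", {
    dens <- density_track(muts, "SNV", cfg$hotspot$binsize,
                          chrom_lengths = sim_cfg$chrom_lengths)
    # demo-scale cutoffs: the synthetic catalog is far denser per kb
    # than a genome-wide one, so the peak cutoff rides on the mean
    hp <- cfg$hotspot
    mean_dens <- mean(unlist(dens$values), na.rm = TRUE)
    hp$c_peak <- max(hp$c_peak, 2.5 * mean_dens)
    hp$c_link <- hp$c_peak / 2
    call_hotspots(dens, hp)
  })
  gene_classes <- .stage("gene-classes",
                         classify_genes(bundle$genes, bundle$rloops))
  assoc <- .stage("hotspot-association",
                  hotspot_gene_association(hot, bundle$genes, gene_classes))
  rates <- .stage("site-rates", site_rates(trcs, muts))
  rate_cmp <- .stage("orientation-rates", {
    # thresholds ride on the pooled densities at demo catalog depth
    gkb <- sum(sim_cfg$chrom_lengths) / 1000
    snv_thr <- 2 * sum(muts$mut_class == "SNV") / gkb
    id_thr <- sum(muts$mut_class != "SNV") / gkb
    orientation_rate_comparison(rates, thresholds = c(snv = snv_thr,
                                                      del = id_thr,
                                                      ins = id_thr))
  })
  burden <- .stage("burden", {
    b <- rloop_burden(muts, bundle$rloops, cfg$burden,
                      status_gene = bundle$genes[
                        bundle$genes$name ==
                          sim_cfg$tumor_specs$target_gene, ])
    list(statuses = b, test = burden_comparison(b))
  })
  sigres <- .stage("signatures", {
    V <- build_sbs96(muts, bundle$genome)
    sp <- cfg$signature
    sp$n_restarts <- min(sp$n_restarts, 8L)
    sp$seed <- seed
    model <- nmf_extract(V, k = ncol(bundle$config$signature_defs), sp)
    probs <- refit_probabilities(V, model$W, sp)
    snv <- muts[muts$mut_class == "SNV", , drop = FALSE]
    chans <- mutation_channels(snv, bundle$genome)
    ok <- !is.na(chans)
    labels <- assign_mutations(snv$sample[ok], chans[ok], probs,
                               seed = seed)
    assigned <- cbind(snv[ok, c("chrom", "start", "sample")],
                      signature = labels)
    sets <- list(all_rloops = bundle$rloops,
                 head_on = trcs[trcs$orientation == "head_on", ],
                 codirectional = trcs[trcs$orientation == "codirectional", ])
    counts <- region_signature_counts(assigned, sets)
    # report the extracted signature matching the planted HO-active one
    planted <- bundle$config$signature_defs[sbs96_labels(), 1]
    match_idx <- which.max(as.vector(.cosine_cols(model$W, matrix(planted))))
    sig_lab <- colnames(model$W)[match_idx]
    rr <- signature_risk_ratio(
      counts$counts[sig_lab, "head_on"], counts$totals[["head_on"]],
      counts$counts[sig_lab, "codirectional"],
      counts$totals[["codirectional"]])
    enriched <- screen$factor[screen$klass == "enriched"]
    fp_sets <- lapply(stats::setNames(enriched, enriched), function(f) {
      pad_intervals(trcs, 10000)
    })
    lf <- if (length(fp_sets) >= 2) {
      factor_signature_logfc(assigned, fp_sets, bundle$rloops)
    } else {
      NULL
    }
    cl <- if (!is.null(lf) && nrow(lf$logfc) >= 2) {
      cluster_factors(lf$logfc, n_clusters = min(7, nrow(lf$logfc)))
    } else {
      NULL
    }
    list(model = model, counts = counts, rr = rr, clusters = cl)
  })
  agg <- .stage("contacts-agg", {
    ho <- trcs[trcs$orientation == "head_on", ]
    cd <- trcs[trcs$orientation == "codirectional", ]
    band_mean <- function(a) {
      off <- attr(a, "offsets")
      sel <- off >= -1e6 & off <= -2e5
      mean(a[sel, sel])
    }
    list(ho = band_mean(aggregate_contacts(ho, bundle$contacts, 1e6)),
         cd = band_mean(aggregate_contacts(cd, bundle$contacts, 1e6)))
  })

  metrics <- list(
    seed = seed,
    n_rloop_peaks = nrow(bundle$rloops),
    n_trc_sites = nrow(trcs),
    n_head_on = sum(trcs$orientation == "head_on"),
    n_codirectional = sum(trcs$orientation == "codirectional"),
    screen_enriched = sum(screen$klass == "enriched"),
    screen_depleted = sum(screen$klass == "depleted"),
    screen_hits = as.list(stats::setNames(screen$klass, screen$factor)),
    orientation_delta = orient$delta,
    orientation_delta_se = orient$se_delta,
    n_hotspots = nrow(hot),
    hotspot_pct_rloop_prone = unname(assoc$percentages["rloop_prone"]),
    snv_rate_ho_fraction = rate_cmp$ho_fraction[rate_cmp$class == "SNV"],
    snv_rate_cd_fraction = rate_cmp$cd_fraction[rate_cmp$class == "SNV"],
    snv_rate_fisher_p = rate_cmp$p_value[rate_cmp$class == "SNV"],
    burden_median_deficient = burden$test$median_deficient,
    burden_median_proficient = burden$test$median_proficient,
    burden_wilcoxon_p = burden$test$p_value,
    nmf_final_kl = sigres$model$kl,
    signature_rr_head_on = sigres$rr$rr,
    n_clusters = if (is.null(sigres$clusters)) 0 else
      length(unique(sigres$clusters$labels)),
    contact_upstream_ho_mean = agg$ho,
    contact_upstream_cd_mean = agg$cd)
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- c(
    sprintf("trcscape demo (seed %d)", seed),
    sprintf("R-loop peaks: %d; TRC sites: %d (%d head-on, %d co-directional)",
            metrics$n_rloop_peaks, metrics$n_trc_sites, metrics$n_head_on,
            metrics$n_codirectional),
    sprintf("factor screen: %d enriched, %d depleted of %d tracks",
            metrics$screen_enriched, metrics$screen_depleted, nrow(screen)),
    sprintf("head-on - co-directional abundance delta: %.3f (SE %.3f)",
            metrics$orientation_delta, metrics$orientation_delta_se),
    sprintf("mutation hotspots: %d (%.1f%% in R-loop-prone genes)",
            metrics$n_hotspots, metrics$hotspot_pct_rloop_prone),
    sprintf("sites >1 SNV/kb: head-on %.3f vs co-directional %.3f (Fisher p = %.3g)",
            metrics$snv_rate_ho_fraction, metrics$snv_rate_cd_fraction,
            metrics$snv_rate_fisher_p),
    sprintf("R-loop burden medians: deficient %.1f vs proficient %.1f (Wilcoxon p = %.3g)",
            metrics$burden_median_deficient,
            metrics$burden_median_proficient, metrics$burden_wilcoxon_p),
    sprintf("signature 1 head-on/co-directional risk ratio: %.2f",
            metrics$signature_rr_head_on))
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(metrics)
}
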