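test_that("coverage_matrix resamples windows with orientation flips", {
  # constant track gives a constant matrix
  tr <- signal_track(list(c1 = rep(3, 100)), 1000)
  sites <- make_trc_sites(4, spacing = 15000, width = 1000, chrom = "c1",
                          offset = 20000)
  m <- coverage_matrix(sites, tr, window_halfwidth = 10000, nbins = 10,
                       orient_by = "fork")
  expect_true(all(m == 3))

  # a delta at a site center lands in a middle column whatever the flip
  v <- rep(0, 100)
  mid <- floor((sites$start[3] + sites$end[3]) / 2)
  v[floor(mid / 1000) + 1] <- 10
  trd <- signal_track(list(c1 = v), 1000)
  m <- coverage_matrix(sites[3, , drop = FALSE], trd,
                       window_halfwidth = 5000, nbins = 10,
                       orient_by = "fork")
  expect_true(which.max(m[1, ]) %in% c(5, 6))

  # hand-built 2-site, 8-bin case matches the per-bp oracle with one
  # flipped row
  set.seed(21)
  v <- runif(60)
  tr <- signal_track(list(c1 = v), 500)
  s2 <- data.frame(chrom = "c1", start = c(9000, 21000),
                   end = c(10000, 22000), name = c("a", "b"), score = 0,
                   strand = c("+", "-"),
                   fork_direction = c("rightward", "leftward"),
                   orientation = "codirectional")
  m <- coverage_matrix(s2, tr, window_halfwidth = 4000, nbins = 8,
                       orient_by = "fork")
  for (i in 1:2) {
    mid <- floor((s2$start[i] + s2$end[i]) / 2)
    want <- oracle_coverage_row(v, 500, mid, 4000, 8, i == 2)
    expect_equal(unclass(m)[i, ], want, tolerance = 1e-10)
  }

  # edge-truncated sites are dropped and reported
  near_edge <- s2
  near_edge$start[1] <- 500; near_edge$end[1] <- 1500
  m <- coverage_matrix(near_edge, tr, window_halfwidth = 4000, nbins = 8,
                       orient_by = "fork")
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "dropped"), 1)
  expect_error(coverage_matrix(s2[0, ], tr, 4000, 8), "empty")
})

test_that("metaprofile averages columns ignoring missing rows", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3))
  mp <- metaprofile(m)
  expect_equal(mp$mean, c(1, 2, 3))
  expect_equal(mp$se, c(0, 0, 0))

  v <- c(1, -2, 3)
  expect_equal(metaprofile(rbind(v, -v))$mean, c(0, 0, 0))

  set.seed(4)
  r <- matrix(rnorm(50), 10)
  r[sample(50, 8)] <- NA
  mp <- metaprofile(r)
  expect_equal(mp$mean, colMeans(r, na.rm = TRUE))
  expect_equal(mp$n, colSums(!is.na(r)))
})

test_that("metagene rescales bodies and respects strand", {
  # uniform track -> flat profile
  tr <- signal_track(list(c1 = rep(2, 50)), 1000)
  genes <- genomic_intervals(c("c1", "c1"), c(10000, 30000),
                             c(16000, 35000), strand = c("+", "-"))
  prof <- metagene(genes, tr, body_bins = 10, flank_bp = 2000,
                   flank_bins = 4)
  expect_true(all(abs(prof$mean - 2) < 1e-12))
  expect_equal(nrow(prof), 18)

  # signal concentrated at each TSS peaks at the profile start
  v <- rep(0, 50)
  v[11] <- 5          # TSS of the + gene (10000)
  v[35] <- 5          # TSS of the - gene (35000)
  trs <- signal_track(list(c1 = v), 1000)
  prof <- metagene(genes, trs, body_bins = 10, flank_bp = 2000,
                   flank_bins = 2)
  body <- prof$mean[prof$segment == "body"]
  expect_equal(which.max(body), 1)

  # 2-gene toy equals the enumerated per-bp oracle
  set.seed(31)
  v <- runif(50)
  trr <- signal_track(list(c1 = v), 1000)
  prof <- metagene(genes, trr, body_bins = 5, flank_bp = 2000,
                   flank_bins = 2)
  oracle_gene <- function(g) {
    edges <- c(seq(genes$start[g] - 2000, genes$start[g], length.out = 3),
               seq(genes$start[g], genes$end[g], length.out = 6)[-1],
               seq(genes$end[g], genes$end[g] + 2000, length.out = 3)[-1])
    row <- vapply(seq_len(length(edges) - 1), function(k) {
      oracle_window_mean(v, 1000, edges[k], edges[k + 1])$mean
    }, numeric(1))
    if (genes$strand[g] == "-") rev(row) else row
  }
  want <- colMeans(rbind(oracle_gene(1), oracle_gene(2)))
  expect_equal(prof$mean, want, tolerance = 1e-10)
})

test_that("screen_factor scores center/flank folds and classifies", {
  sites <- make_trc_sites(6, spacing = 300000, width = 1000,
                          chrom = "c1", offset = 120000)
  cl <- attr(sites, "chrom_length")
  sp <- screen_params(flank_offset = 1e5, window_halfwidth = 1e5)

  flat <- signal_track(list(c1 = rep(2, ceiling(cl / 1000))), 1000)
  res <- screen_factor(sites, flat, sp, "flat")
  expect_equal(res$rms_up, 0)
  expect_equal(res$rms_down, 0)
  expect_equal(res$klass, "none")

  # center exactly 2x both flanks -> rms 1.0, enriched
  v <- rep(1, ceiling(cl / 1000))
  mids <- floor((sites$start + sites$end) / 2)
  for (m in mids) {
    bins <- which(abs((seq_along(v) - 0.5) * 1000 - m) <= 10000)
    v[bins] <- 2
  }
  tr2 <- signal_track(list(c1 = v), 1000)
  res <- screen_factor(sites, tr2, sp, "double")
  expect_equal(res$rms_up, 1, tolerance = 0.05)
  expect_equal(res$rms_down, 1, tolerance = 0.05)
  expect_equal(res$klass, "enriched")

  # center at 0.8x both flanks -> rms ~ -0.322, depleted
  v08 <- rep(1, ceiling(cl / 1000))
  for (m in mids) {
    bins <- which(abs((seq_along(v08) - 0.5) * 1000 - m) <= 10000)
    v08[bins] <- 0.8
  }
  res <- screen_factor(sites, signal_track(list(c1 = v08), 1000), sp, "low")
  expect_equal(res$rms_up, log2(0.8), tolerance = 0.02)
  expect_equal(res$klass, "depleted")

  # zero flank signal flags the factor unscorable
  vz <- rep(0, ceiling(cl / 1000))
  for (m in mids) vz[floor(m / 1000) + 1] <- 1
  res <- screen_factor(sites, signal_track(list(c1 = vz), 1000), sp, "z")
  expect_true(res$unscorable)
  expect_equal(res$klass, "none")
})

test_that("screen recovers planted enrichment classes from tracks", {
  sites <- make_trc_sites(120, spacing = 120000, width = 1000)
  cl <- c(chrS = attr(sites, "chrom_length"))
  specs <- c(make_factor_specs(4, center_fold = 1.5, noise_cv = 0.1,
                               prefix = "enr"),
             make_factor_specs(2, center_fold = 0.6, noise_cv = 0.1,
                               prefix = "dep"),
             make_factor_specs(4, center_fold = 1, noise_cv = 0.1,
                               prefix = "nul"))
  tracks <- lapply(seq_along(specs), function(i) {
    simulate_factor_track(sites, specs[[i]], cl, 1000, seed = 100 + i)
  })
  names(tracks) <- names(specs)
  res <- screen_factors(sites, tracks, screen_params())
  planted <- vapply(specs, function(s) s$planted_class, character(1))
  expect_equal(res$klass[planted == "enriched"], rep("enriched", 4))
  expect_equal(res$klass[planted == "depleted"], rep("depleted", 2))
  expect_equal(res$klass[planted == "none"], rep("none", 4))
})

test_that("compare_orientations detects head-on-only enrichment", {
  sites <- make_trc_sites(200, spacing = 80000, width = 1000)
  cl <- c(chrS = attr(sites, "chrom_length"))
  sp <- screen_params()

  # identical planted folds: delta within noise of zero
  tr0 <- simulate_factor_track(sites, list(center_fold = 2, flank_level = 1,
                                           noise_cv = 0.1,
                                           orientation_bias = 1),
                               cl, 1000, seed = 5)
  r0 <- compare_orientations(sites, tr0, sp)
  expect_lt(abs(r0$delta), 3 * r0$se_delta)

  # head-on bias recovered
  tr1 <- simulate_factor_track(sites, list(center_fold = 2, flank_level = 1,
                                           noise_cv = 0.1,
                                           orientation_bias = 1.5),
                               cl, 1000, seed = 6)
  r1 <- compare_orientations(sites, tr1, sp)
  expect_gt(r1$delta, 3 * r1$se_delta)

  # label permutation null: delta within 3 SE of zero
  set.seed(9)
  perm <- sites
  perm$orientation <- sample(perm$orientation)
  rp <- compare_orientations(perm, tr1, sp)
  expect_lt(abs(rp$delta), 3 * rp$se_delta)

  # one empty class gives missing means
  ho_only <- sites[sites$orientation == "head_on", ]
  rh <- compare_orientations(ho_only, tr1, sp)
  expect_true(is.na(rh$cd_mean))
  expect_true(is.na(rh$delta))
})

test_that("enrichment_score matches the walk oracle and limits", {
  # all members at the head of the list push ES toward +1
  metrics <- setNames(seq(10, 1), letters[1:10])
  es_top <- enrichment_score(metrics, c("a", "b"), n_perm = 99, seed = 1)
  expect_gt(es_top$es, 0.7)
  expect_lt(es_top$p_value, 0.1)

  # uniform interleaving with weight 0 stays near zero
  met <- setNames(rep(1, 10), letters[1:10])
  es0 <- enrichment_score(met, letters[seq(1, 10, 2)], weight_p = 0,
                          n_perm = 49, seed = 1)
  expect_lt(abs(es0$es), 0.25)

  # random lists match the explicit-walk oracle exactly
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    m <- setNames(round(rnorm(n), 3), paste0("f", 1:n))
    hitset <- sample(names(m), sample(1:(n - 1), 1))
    got <- enrichment_score(m, hitset, weight_p = 1, n_perm = 9, seed = 2)
    want <- oracle_es(m, names(m) %in% hitset, 1)
    expect_equal(got$es, want, tolerance = 1e-12)
  }
  expect_error(enrichment_score(metrics, character(0)), "empty")
  expect_error(enrichment_score(metrics, "zz"), "subset")
})

test_that("aggregate_contacts averages oriented submatrices", {
  # uniform map -> uniform mean; single site returns its own submatrix
  n <- 61
  u <- matrix(2, n, n)
  cm <- contact_map(list(c1 = u), 10000)
  site <- make_trc_sites(1, chrom = "c1", offset = 3e5, width = 1000)
  agg <- aggregate_contacts(site, cm, 1e5)
  expect_true(all(agg == 2))
  expect_equal(dim(agg), c(21, 21))

  # orientation flip: a leftward site sees the matrix rotated 180 degrees
  m <- matrix(0, n, n)
  m[1:10, 1:10] <- 5
  m <- (m + t(m)) / 2
  cmx <- contact_map(list(c1 = m), 10000)
  s_r <- site; s_r$fork_direction <- "rightward"
  s_l <- site; s_l$fork_direction <- "leftward"
  a_r <- aggregate_contacts(s_r, cmx, 2e5)
  a_l <- aggregate_contacts(s_l, cmx, 2e5)
  expect_equal(unname(as.matrix(a_l)),
               unname(as.matrix(a_r)[rev(seq_len(41)), rev(seq_len(41))]),
               ignore_attr = TRUE)

  # symmetry preserved when all sites share fork direction
  set.seed(17)
  r <- matrix(runif(n * n), n)
  r <- (r + t(r)) / 2
  cmr <- contact_map(list(c1 = r), 10000)
  sites <- make_trc_sites(3, spacing = 50000, chrom = "c1",
                          offset = 250000, width = 1000)
  sites$fork_direction <- "rightward"
  ar <- aggregate_contacts(sites, cmr, 1e5)
  expect_equal(unname(as.matrix(ar)), t(unname(as.matrix(ar))),
               tolerance = 1e-12)
  # edge sites dropped and reported
  far <- make_trc_sites(1, chrom = "c1", offset = 1e4, width = 1000)
  expect_error(aggregate_contacts(far, cmr, 1e5), "usable")
})

test_that("peak annotation follows promoter > five_prime > body precedence", {
  genes <- data.frame(chrom = "c1", start = c(10000, 50000),
                      end = c(20000, 60000), name = c("gA", "gB"),
                      score = 0, strand = c("+", "-"))
  peaks <- genomic_intervals(
    rep("c1", 5),
    c(9900, 11200, 14000, 30000, 59900),
    c(10100, 11800, 15000, 31000, 60100))
  ann <- annotate_peaks(peaks, genes, promoter_bp = 1000,
                        five_prime_bp = 2000)
  # gB is minus-strand: its TSS sits at the gene end
  expect_equal(ann, c("promoter", "five_prime", "body", "intergenic",
                      "promoter"))

  # overlapping genes: precedence then nearest TSS
  genes2 <- rbind(genes,
                  data.frame(chrom = "c1", start = 12000, end = 30000,
                             name = "gC", score = 0, strand = "+"))
  mid_peak <- genomic_intervals("c1", 12400, 12600)
  expect_equal(annotate_peaks(mid_peak, genes2), "promoter")  # gC TSS 12000
})

test_that("gc_content counts G+C excluding N", {
  seqs <- c(c1 = "GCGCATATACGTN")
  expect_equal(gc_content(seqs, genomic_intervals("c1", 0, 4)), 1)
  expect_equal(gc_content(seqs, genomic_intervals("c1", 4, 8)), 0)
  expect_equal(gc_content(seqs, genomic_intervals("c1", 8, 13)), 0.5)
  expect_true(is.na(gc_content(c(c1 = "NNNN"),
                               genomic_intervals("c1", 0, 4))))
  expect_error(gc_content(seqs, genomic_intervals("c1", 0, 99)), "exceeds")
})

test_that("mirroring the genome leaves oriented profiles unchanged", {
  # reverse the coordinate system of a one-chromosome toy: tracks and
  # intervals mirrored, fork directions and strands swapped
  set.seed(23)
  L <- 2e5
  v <- runif(L / 1000)
  tr <- signal_track(list(c1 = v), 1000)
  sites <- make_trc_sites(4, spacing = 30000, width = 1000, chrom = "c1",
                          offset = 40000)
  sp <- screen_params(flank_offset = 3e4, window_halfwidth = 3e4)
  res <- screen_factor(sites, tr, sp)

  mirror <- signal_track(list(c1 = rev(v)), 1000)
  msites <- sites
  msites$start <- L - sites$end
  msites$end <- L - sites$start
  msites$strand <- ifelse(sites$strand == "+", "-", "+")
  msites$fork_direction <- ifelse(sites$fork_direction == "rightward",
                                  "leftward", "rightward")
  mres <- screen_factor(msites, mirror, sp)
  expect_equal(res$rms_up, mres$rms_up, tolerance = 1e-10)
  expect_equal(res$rms_down, mres$rms_down, tolerance = 1e-10)

  p1 <- metaprofile(coverage_matrix(sites, tr, 3e4, 20, "fork"))
  p2 <- metaprofile(coverage_matrix(msites, mirror, 3e4, 20, "fork"))
  expect_equal(p1$mean, p2$mean, tolerance = 1e-10)
})
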