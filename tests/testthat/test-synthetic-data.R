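test_that("simulate_rfd realizes the origin/terminus model", {
  # single origin: +1 right, -1 left
  v <- simulate_rfd(5000, 10000, 1000, terminus_width = 2000)
  expect_true(all(v[1:5] == -1))
  expect_true(all(v[6:10] == 1))

  # bin centered exactly on the midpoint between two origins is 0
  v <- simulate_rfd(c(2000, 8000), 10000, 400, terminus_width = 4000)
  expect_equal(v[13], 0)  # bin 13 centered at 5000 = (2000 + 8000) / 2
  expect_true(all(v >= -1 & v <= 1))

  # arbitrary origin set equals per-bin evaluation of the ramp
  set.seed(5)
  for (rep in 1:20) {
    o <- sort(sample(1000:49000, sample(2:6, 1)))
    w <- sample(c(2000, 5000), 1)
    bs <- sample(c(250, 500), 1)
    got <- simulate_rfd(o, 50000, bs, terminus_width = w)
    centers <- (seq_along(got) - 0.5) * bs
    want <- vapply(centers, function(x) {
      i <- findInterval(x, o)
      if (i == 0) return(-1)
      if (i == length(o)) return(1)
      m <- (o[i] + o[i + 1]) / 2
      ww <- min(w, o[i + 1] - o[i])
      max(-1, min(1, 1 - 2 * (x - (m - ww / 2)) / ww))
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }

  expect_true(all(is.na(simulate_rfd(numeric(0), 5000, 500))))
  expect_error(simulate_rfd(6000, 5000, 500), "within")
})

test_that("factor tracks carry the planted center effect", {
  sites <- make_trc_sites(40, spacing = 100000, width = 1000,
                          offset = 50000)
  cl <- c(chrS = attr(sites, "chrom_length"))

  # null fold: site means equal flank means (no noise)
  spec0 <- list(center_fold = 1, flank_level = 2, noise_cv = 0)
  tr <- simulate_factor_track(sites, spec0, cl, 1000, seed = 1)
  expect_true(all(tr$values$chrS == 2))

  # exact doubling without noise
  spec2 <- list(center_fold = 2, flank_level = 1, noise_cv = 0)
  tr <- simulate_factor_track(sites, spec2, cl, 1000, seed = 1)
  mid <- floor((sites$start[1] + sites$end[1]) / 2)
  bin <- floor(mid / 1000) + 1
  expect_equal(tr$values$chrS[bin], 2)
  expect_equal(tr$values$chrS[bin + 30], 1)
  expect_true(all(tr$values$chrS >= 0))
  expect_error(simulate_factor_track(sites, list(center_fold = 0,
                                                 flank_level = 1),
                                     cl, 1000, 1), "center_fold")

  # Monte-Carlo: empirical center/flank ratio within 3 SE of the fold
  sites5 <- make_trc_sites(500, spacing = 60000, width = 1000,
                           offset = 50000)
  cl5 <- c(chrS = attr(sites5, "chrom_length"))
  spec <- list(center_fold = 1.5, flank_level = 1, noise_cv = 0.1)
  tr <- simulate_factor_track(sites5, spec, cl5, 1000, seed = 9)
  mids <- floor((sites5$start + sites5$end) / 2)
  cbin <- floor(mids / 1000) + 1
  centers <- tr$values$chrS[cbin]
  flanks <- tr$values$chrS[cbin + 25]
  ratio <- mean(centers) / mean(flanks)
  se <- ratio * sqrt(var(centers) / (mean(centers)^2 * 500) +
                     var(flanks) / (mean(flanks)^2 * 500))
  expect_lt(abs(ratio - 1.5), 3 * se)
})

test_that("bundle generation is deterministic and honours degenerate configs", {
  cfg <- simulation_config(
    seed = 5, chrom_lengths = c(cA = 6e5), n_genes = 20,
    origin_spacing = 80000, edge_margin = 4e4,
    tumor_specs = list(n_tumors = 4, mutations_per_tumor = 60,
                       deficient_fraction = 0),
    signature_defs = local({
      m <- matrix(c(1), 1, 1,
                  dimnames = list("A[C>T]A", "sigA"))
      m
    }))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  b1 <- simulate_genome(cfg, d1)
  b2 <- simulate_genome(cfg, d2)
  for (f in c("fasta", "genes", "rloops", "rfd", "mutations")) {
    expect_identical(readBin(b1$paths[[f]], "raw", 2e6),
                     readBin(b2$paths[[f]], "raw", 2e6),
                     label = f)
  }
  # deficient_fraction = 0 leaves every tumor proficient in the truth
  expect_true(all(b1$tumor_truth$status == "proficient"))
  # single-channel signature: every SNV is C>T at ACA (or reverse
  # complement TGT with G>A)
  mu <- b1$mutations
  ctx <- mutation_channels(mu, b1$genome)
  expect_true(all(ctx[mu$mut_class == "SNV"] == "A[C>T]A"))

  # n_genes = 0: no genes or R-loops, valid RFD
  cfg0 <- simulation_config(seed = 2, chrom_lengths = c(cA = 4e5),
                            n_genes = 0, edge_margin = 1e4,
                            origin_spacing = 60000)
  b0 <- simulate_genome(cfg0)
  expect_equal(nrow(b0$genes), 0)
  expect_equal(nrow(b0$rloops), 0)
  expect_true(all(b0$rfd$values$cA >= -1 & b0$rfd$values$cA <= 1,
                  na.rm = TRUE))

  # infeasible gene load errors
  expect_error(simulate_genome(simulation_config(
    seed = 1, chrom_lengths = c(cA = 2e5), n_genes = 5000,
    edge_margin = 1e4)), "infeasible")
})

test_that("planted mutation effects and channel mixtures are recovered", {
  sigs <- trcscape:::.demo_signatures(k = 3)
  cfg <- simulation_config(
    seed = 8, chrom_lengths = c(cA = 2e6, cB = 2e6), n_genes = 400,
    edge_margin = 5e4, signature_defs = sigs,
    tumor_specs = list(n_tumors = 12, mutations_per_tumor = 1500,
                       # fixed mixture matrix: the pooled spectrum is then
                       # exactly multinomial around the planted mixture
                       signature_mixture = matrix(1 / 3, 3, 12),
                       ho_rate_multiplier = 1, deficient_fraction = 0))
  b <- simulate_genome(cfg)
  mu <- b$mutations
  truth <- b$mutation_truth

  # null HO multiplier: per-kb rates at HO vs CD within noise of equal
  tt <- b$site_truth[b$site_truth$is_trc, ]
  rates <- site_rates(tt, mu)
  ho <- rates$snv_per_kb[rates$orientation == "head_on"]
  cd <- rates$snv_per_kb[rates$orientation == "codirectional"]
  se <- sqrt(var(ho) / length(ho) + var(cd) / length(cd))
  expect_lt(abs(mean(ho) - mean(cd)), 3 * se)

  # channel conservation: per-tumor SBS96 spectra match the planted
  # mixture within multinomial error (chi-square GOF on pooled counts)
  V <- build_sbs96(mu, b$genome)
  pooled <- rowSums(V)
  mix_planted <- rowMeans(sweep(sigs[sbs96_labels(), ], 2,
                                colSums(sigs[sbs96_labels(), ]), "/"))
  keep <- mix_planted > 0
  gof <- suppressWarnings(
    stats::chisq.test(pooled[keep], p = mix_planted[keep] / sum(mix_planted[keep])))
  expect_gt(gof$p.value, 0.001)
  # no mass on channels outside the planted signatures
  expect_equal(sum(pooled[!keep]), 0)

  # orientation balance under an unbiased config
  n_ho <- sum(tt$orientation == "head_on")
  n <- nrow(tt)
  expect_lt(abs(n_ho - n / 2), 3 * sqrt(n * 0.25))
})

test_that("simulated contacts decay as a power law with planted compaction", {
  sites <- rbind(make_trc_sites(1, width = 1000, offset = 1.5e6,
                                chrom = "c1"),
                 make_trc_sites(1, width = 1000, offset = 1.5e6,
                                chrom = "c2"))
  # site 1 head-on (rightward fork into a minus-strand gene), site 2
  # co-directional
  sites$strand <- c("-", "+")
  sites$orientation <- c("head_on", "codirectional")
  cl <- c(c1 = 3e6, c2 = 3e6)

  cfg <- simulation_config(seed = 1, chrom_lengths = cl, n_genes = 0,
                           edge_margin = 1e4,
                           contact_spec = list(binsize = 10000, alpha = 1,
                                               upstream_compaction_fold = 1))
  cm <- simulate_contacts(cfg, sites, cl)
  m <- as.matrix(cm$matrices$c1)
  # fold 1: pure power-law decay
  expect_equal(m[1, 11], (10 + 1)^-1)
  expect_equal(m, t(m))

  cfg2 <- simulation_config(seed = 1, chrom_lengths = cl, n_genes = 0,
                            edge_margin = 1e4,
                            contact_spec = list(binsize = 10000, alpha = 1,
                                                upstream_compaction_fold = 3))
  # only site 1 is head-on; site 2 (c2) is co-directional
  expect_equal(sites$orientation, c("head_on", "codirectional"))
  cm2 <- simulate_contacts(cfg2, sites, cl)
  agg_ho <- aggregate_contacts(sites[1, , drop = FALSE], cm2, 1.2e6)
  agg_cd <- aggregate_contacts(sites[2, , drop = FALSE], cm2, 1.2e6)
  off <- attr(agg_ho, "offsets")
  band <- off >= -1e6 & off <= -2e5
  # upstream compaction visible at the head-on site only
  expect_gt(mean(agg_ho[band, band]) / mean(agg_cd[band, band]), 2)
  down <- off >= 2e5 & off <= 1e6
  expect_equal(mean(agg_cd[band, band]), mean(agg_cd[down, down]),
               tolerance = 1e-9)

  expect_error(simulate_contacts(simulation_config(
    seed = 1, chrom_lengths = cl, n_genes = 0, edge_margin = 1e4,
    contact_spec = list(alpha = -1)), sites, cl), "alpha")
})
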