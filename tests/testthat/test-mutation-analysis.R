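test_that("density tracks conserve event counts at per-kb scale", {
  mu <- make_mut(rep("S1", 10), rep("c1", 10), rep(500, 10), "C", "T")
  tr <- density_track(mu, "SNV", 1000, chrom_lengths = c(c1 = 3000))
  expect_equal(tr$values$c1, c(10, 0, 0))

  mu0 <- mu[0, ]
  tr0 <- density_track(mu0, "SNV", 1000, chrom_lengths = c(c1 = 2000))
  expect_equal(tr0$values$c1, c(0, 0))

  set.seed(3)
  mu <- make_mut("S1", "c1", sample(1:5000, 200, TRUE), "C", "T")
  tr <- density_track(mu, "SNV", 500, chrom_lengths = c(c1 = 5000))
  expect_equal(sum(unlist(tr$values)) * 500 / 1000, 200)
})

test_that("hotspot calling implements the two-threshold merge rule", {
  hp <- hotspot_params(binsize = 1000, c_peak = 0.25, c_link = 0.125,
                       min_len = 200, max_gap = 2000)
  # everything below c_peak: nothing called
  tr <- signal_track(list(c1 = rep(0.2, 10)), 1000)
  expect_equal(nrow(call_hotspots(tr, hp)), 0)

  # a single run of 3 qualifying bins becomes exactly that interval
  v <- c(0, 0.3, 0.3, 0.3, 0, 0, 0, 0, 0, 0)
  hs <- call_hotspots(signal_track(list(c1 = v), 1000), hp)
  expect_equal(hs$start, 1000)
  expect_equal(hs$end, 4000)

  # linkable gap merges; sub-link gap does not
  v_link <- c(0.3, 0.2, 0.3, rep(0, 7))
  hs <- call_hotspots(signal_track(list(c1 = v_link), 1000), hp)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$end - hs$start, 3000)
  v_break <- c(0.3, 0.1, 0.3, rep(0, 7))
  hs <- call_hotspots(signal_track(list(c1 = v_break), 1000), hp)
  expect_equal(nrow(hs), 2)

  # property: matches the exhaustive scan oracle on random tracks
  set.seed(41)
  for (rep in 1:150) {
    n <- sample(10:60, 1)
    v <- round(runif(n, 0, 0.5), 2)
    v[sample(n, n %/% 10)] <- NA
    gap <- sample(c(1000, 2000, 3000), 1)
    minl <- sample(c(1000, 2000), 1)
    hp <- hotspot_params(1000, 0.25, 0.125, minl, gap)
    got <- call_hotspots(signal_track(list(x = v), 1000), hp)
    want <- oracle_hotspots(v, 1000, 0.25, 0.125, minl, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("gene classification gives peaks precedence over expression", {
  genes <- data.frame(chrom = "c1", start = c(0, 2000, 4000),
                      end = c(1000, 3000, 5000),
                      name = c("g1", "g2", "g3"),
                      score = c(0, 5, 0), strand = "+",
                      expression = c(0, 5, 0))
  peaks <- genomic_intervals("c1", 100, 300)
  cls <- classify_genes(genes, peaks)
  expect_equal(cls, c("rloop_prone", "expressed_reluctant", "silenced"))
})

test_that("hotspot-gene association reports percentages and Yates tests", {
  genes <- data.frame(chrom = "c1",
                      start = seq(0, 39000, 1000),
                      end = seq(0, 39000, 1000) + 900,
                      name = sprintf("g%d", 1:40), score = 0, strand = "+")
  classes <- rep(c("rloop_prone", "expressed_reluctant", "silenced",
                   "silenced"), 10)
  # plant hotspots preferentially in rloop_prone genes
  hs_genes <- c(which(classes == "rloop_prone")[1:8],
                which(classes == "silenced")[1:2])
  hotspots <- genomic_intervals("c1", genes$start[hs_genes] + 100,
                                genes$start[hs_genes] + 500)
  res <- hotspot_gene_association(hotspots, genes, classes)
  expect_equal(unname(res$percentages["rloop_prone"]), 80)
  expect_equal(which.max(res$percentages), c(rloop_prone = 1))
  expect_lt(res$pairwise$p_value[res$pairwise$class_a == "rloop_prone" &
                                   res$pairwise$class_b == "silenced"],
            0.05)
  # pairwise statistic equals the hand Yates formula on the same table
  tab <- res$table[c("rloop_prone", "silenced"), ]
  want <- oracle_yates_stat(tab)
  got <- res$pairwise$statistic[res$pairwise$class_a == "rloop_prone" &
                                  res$pairwise$class_b == "silenced"]
  expect_equal(got, want, tolerance = 1e-12)

  # all hotspots in one class
  hs2 <- genomic_intervals("c1", genes$start[classes == "rloop_prone"] + 100,
                           genes$start[classes == "rloop_prone"] + 500)
  res2 <- hotspot_gene_association(hs2, genes, classes)
  expect_equal(unname(res2$percentages),
               c(100, 0, 0))
  expect_error(hotspot_gene_association(hotspots[0, ], genes, classes),
               "at least one")
})

test_that("site rates use half-open overlap by start position", {
  sites <- genomic_intervals("c1", c(1000, 5000), c(3000, 6000))
  mu <- rbind(
    make_mut("S1", "c1", c(1001, 1500, 2999), "C", "T"),   # 3 SNVs site 1
    make_mut("S1", "c1", 3001, "CA", "C"),                 # start 3000: out
    make_mut("S1", "c1", 2001, "CA", "C"),                 # DEL in site 1
    make_mut("S1", "c1", 5500, "G", "GT"))                 # INS in site 2
  r <- site_rates(sites, mu)
  expect_equal(r$snv_per_kb, c(1.5, 0))
  expect_equal(r$del_per_kb, c(0.5, 0))
  expect_equal(r$ins_per_kb, c(0, 1))
  expect_error(site_rates(genomic_intervals("c1", 5, 5 + 0), mu))

  # random catalog equals brute-force per-site counts
  set.seed(6)
  sites <- genomic_intervals("c1", s <- seq(0, 9000, 1000) + 100, s + 900)
  mu <- make_mut("S1", "c1", sample(1:10000, 300, TRUE), "C", "T")
  r <- site_rates(sites, mu)
  for (i in seq_len(nrow(sites))) {
    want <- sum(mu$start >= sites$start[i] & mu$start < sites$end[i])
    expect_equal(r$snv_per_kb[i] * (sites$end[i] - sites$start[i]) / 1000,
                 want)
  }
  # conservation: per-site totals equal catalog mutations inside any site
  total <- sum(r$snv_per_kb * r$length_kb)
  inside <- sum(trcscape:::points_in_intervals(mu$chrom, mu$start, sites))
  expect_equal(total, inside)
})

test_that("orientation rate comparison tests head-on excess one-tailed", {
  sites <- make_trc_sites(40, spacing = 5000, width = 1000, offset = 1000)
  rates <- site_rates(sites, make_mut("S1", "chrS", 1, "C", "T")[0, ])
  rates$snv_per_kb <- ifelse(rates$orientation == "head_on", 2, 0.5)
  res <- orientation_rate_comparison(rates)
  snv <- res[res$class == "SNV", ]
  expect_equal(snv$ho_fraction, 1)
  expect_equal(snv$cd_fraction, 0)
  expect_lt(snv$p_value, 1e-6)

  # identical rate distributions: fractions equal, p in the null range
  rates$snv_per_kb <- rep(c(2, 2), length.out = nrow(rates))
  res0 <- orientation_rate_comparison(rates)
  expect_equal(res0$ho_fraction[1], res0$cd_fraction[1])
  expect_gt(res0$p_value[1], 0.5)

  # one orientation absent errors
  ho_only <- rates[rates$orientation == "head_on", ]
  expect_error(orientation_rate_comparison(ho_only), "orientation")

  # Fisher one-tailed p equals the enumeration oracle on small tables
  set.seed(8)
  for (rep in 1:30) {
    tab <- matrix(sample(0:6, 4, TRUE), 2)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) next
    want <- oracle_fisher_greater(tab)
    got <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("tumor status requires a disrupting mutation inside the gene", {
  gene <- genomic_intervals("c1", 1000, 2000, name = "G")
  inside_missense <- make_mut("T1", "c1", 1500, "C", "T", "missense")
  inside_silent <- make_mut("T1", "c1", 1500, "C", "T", "synonymous")
  outside_missense <- make_mut("T1", "c1", 5000, "C", "T", "missense")
  expect_equal(classify_tumor_status(inside_missense, gene), "deficient")
  expect_equal(classify_tumor_status(inside_silent, gene), "proficient")
  expect_equal(classify_tumor_status(outside_missense, gene), "proficient")
})

test_that("rloop burden counts peak-union overlaps above the size filter", {
  peaks <- genomic_intervals("c1", c(1000, 3000), c(2000, 4000))
  mu <- rbind(
    make_mut(rep("T1", 3), "c1", c(1100, 1200, 3500), "C", "T"),
    make_mut(rep("T2", 2), "c1", c(100, 5000), "C", "T"))
  bp <- burden_params(min_mutations = 2)
  res <- rloop_burden(mu, peaks, bp)
  expect_equal(res$burden[res$sample == "T1"], 3)
  expect_equal(res$burden[res$sample == "T2"], 0)

  # the min_mutations filter excludes small tumors
  res2 <- rloop_burden(mu, peaks, burden_params(min_mutations = 3))
  expect_equal(res2$sample, "T1")

  # invariant to splitting a peak into abutting sub-peaks and to order
  split_peaks <- genomic_intervals("c1", c(1000, 1500, 3000),
                                   c(1500, 2000, 4000))
  res3 <- rloop_burden(mu[sample(nrow(mu)), ], split_peaks, bp)
  expect_equal(res3$burden[res3$sample == "T1"], 3)

  # brute-force cross-check on a random catalog
  set.seed(10)
  mu <- make_mut(sample(paste0("T", 1:4), 120, TRUE), "c1",
                 sample(1:6000, 120, TRUE), "C", "T")
  res4 <- rloop_burden(mu, peaks, burden_params(min_mutations = 0))
  for (s in res4$sample) {
    sub <- mu[mu$sample == s, ]
    want <- sum((sub$start >= 1000 & sub$start < 2000) |
                  (sub$start >= 3000 & sub$start < 4000))
    expect_equal(res4$burden[res4$sample == s], want)
  }
})

test_that("burden comparison runs exact or approximate Wilcoxon", {
  st <- data.frame(sample = paste0("T", 1:6),
                   n_mutations = 100,
                   burden = c(1, 2, 3, 10, 11, 12),
                   status = rep(c("proficient", "deficient"), each = 3))
  res <- burden_comparison(st)
  expect_equal(res$median_deficient, 11)
  # exact enumeration: most extreme of choose(6,3) = 20 partitions
  expect_equal(res$p_value, 2 / 20)
  expect_match(res$method, "exact")

  # identical groups: p in the null region
  st$burden <- rep(c(5, 6, 7), 2)
  expect_gt(burden_comparison(st)$p_value, 0.9)

  st_missing <- st[st$status == "proficient", ]
  expect_error(burden_comparison(st_missing), "deficient")

  # implementation matches enumeration oracle, ties included
  set.seed(12)
  for (rep in 1:25) {
    x <- sample(1:6, sample(3:6, 1), TRUE)
    y <- sample(1:6, sample(3:6, 1), TRUE)
    got <- trcscape:::wilcoxon_rank_sum(x, y)
    expect_equal(got$p_value, oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12)
  }
  # and agrees with stats::wilcox.test when ties are absent and n large
  set.seed(13)
  x <- rnorm(30); y <- rnorm(25) + 0.5
  got <- trcscape:::wilcoxon_rank_sum(x, y)
  want <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
})

test_that("within-gene shuffling preserves lengths and hosts", {
  genes <- genomic_intervals("c1", c(0, 10000), c(5000, 20000),
                             name = c("g1", "g2"))
  iv <- genomic_intervals("c1", c(1000, 12000), c(1500, 12100))
  sh <- shuffle_within_genes(iv, genes, seed = 4)
  expect_equal(sh$end - sh$start, iv$end - iv$start)
  gi <- trcscape:::point_interval_index(sh$chrom,
                                        floor((sh$start + sh$end) / 2),
                                        genes)
  expect_equal(genes$name[gi], c("g1", "g2"))
  # seeded reproducibility
  expect_equal(shuffle_within_genes(iv, genes, seed = 4), sh)
  expect_false(identical(shuffle_within_genes(iv, genes, seed = 5)$start,
                         sh$start))

  # interval as long as its gene is forced in place
  iv_full <- genomic_intervals("c1", 0, 5000)
  expect_equal(shuffle_within_genes(iv_full, genes, seed = 1)$start, 0)

  # Monte-Carlo null: uniform mutations give shuffled burden compatible
  # with the observed burden
  set.seed(14)
  mu <- make_mut("T1", "c1", sample(1:20000, 4000, TRUE), "C", "T")
  obs <- sum(trcscape:::points_in_intervals(mu$chrom, mu$start, iv))
  shuffled <- vapply(1:40, function(s) {
    ivs <- shuffle_within_genes(iv, genes, seed = s)
    sum(trcscape:::points_in_intervals(mu$chrom, mu$start, ivs))
  }, numeric(1))
  expect_lt(abs(obs - mean(shuffled)), 3 * max(stats::sd(shuffled), 1))
})

test_that("overlap percentage reproduces the worked example and bounds", {
  expect_identical(overlap_percentage(2771, 1951), 70.4)
  expect_equal(overlap_percentage(37, 37), 100)
  expect_equal(overlap_percentage(12, 0), 0)
  expect_error(overlap_percentage(0, 0), "total")
  expect_error(overlap_percentage(10, 11), "overlap")
})
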