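# Independent brute-force oracles. Each re-derives the quantity from its
# definition with plain loops, sharing no code with the implementation.

# per-bin RFD from right/left counts
oracle_rfd <- function(r, l) {
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    tot <- r[i] + l[i]
    out[i] <- if (is.na(tot) || tot == 0) NA_real_ else (r[i] - l[i]) / tot
  }
  out
}

# per-bp length-weighted mean of a binned track over [s, e)
oracle_window_mean <- function(v, bs, s, e) {
  num <- 0; den <- 0
  for (p in seq(s, e - 1)) {          # one term per base pair
    b <- floor(p / bs) + 1
    if (b >= 1 && b <= length(v) && !is.na(v[b])) {
      num <- num + v[b]
      den <- den + 1
    }
  }
  list(mean = if (den > 0) num / den else NA_real_,
       covered_fraction = den / (e - s))
}

# two-threshold broad-region caller, per-bin scan
oracle_hotspots <- function(v, bs, c_peak, c_link, min_len, max_gap) {
  v[is.na(v)] <- -Inf
  n <- length(v)
  regions <- list()
  cur <- NULL
  i <- 1
  while (i <= n) {
    if (v[i] >= c_peak) {
      j <- i
      while (j < n && v[j + 1] >= c_peak) j <- j + 1
      if (is.null(cur)) {
        cur <- c(i, j)
      } else {
        gap_bins <- i - cur[2] - 1
        link_ok <- gap_bins == 0 ||
          all(v[(cur[2] + 1):(i - 1)] >= c_link)
        if (gap_bins * bs <= max_gap && link_ok) {
          cur[2] <- j
        } else {
          regions[[length(regions) + 1]] <- cur
          cur <- c(i, j)
        }
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!is.null(cur)) regions[[length(regions) + 1]] <- cur
  out <- do.call(rbind, Filter(function(r) {
    (r[2] - r[1] + 1) * bs >= min_len
  }, regions))
  if (is.null(out)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = (out[, 1] - 1) * bs, end = out[, 2] * bs)
}

# one-tailed (greater) Fisher p for a 2x2 table by enumeration of all
# column assignments with fixed margins
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]; b <- tab[2, 1]; c0 <- tab[1, 2]; d <- tab[2, 2]
  r1 <- a + c0          # row 1 total ("above")
  n <- a + b + c0 + d
  c1 <- a + b           # column 1 total
  items <- c(rep(1, r1), rep(0, n - r1))
  combs <- utils::combn(n, c1)
  as <- colSums(matrix(items[combs], nrow = c1))
  mean(as >= a)
}

# Yates-corrected chi-square statistic from the hand formula
oracle_yates_stat <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c0 <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c0 + d
  num <- (abs(a * d - b * c0) - n / 2)
  if (num < 0) num <- 0
  num^2 * n / ((a + b) * (c0 + d) * (a + c0) * (b + d))
}

# two-tailed exact Wilcoxon rank-sum p by full enumeration (valid with
# ties); |W - E[W]| >= |w - E[W]| convention
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  combs <- utils::combn(nx + ny, nx)
  hits <- 0
  for (k in seq_len(ncol(combs))) {
    w <- sum(r[combs[, k]]) - nx * (nx + 1) / 2
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(combs)
}

# weighted-KS enrichment score by an explicit walk
oracle_es <- function(metrics, hits, p) {
  ord <- order(metrics, decreasing = TRUE)
  metrics <- metrics[ord]; hits <- hits[ord]
  N <- length(metrics); Nh <- sum(hits)
  w <- abs(metrics)^p
  hw <- sum(w[hits])
  best <- 0; cur <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      cur <- cur + if (hw > 0) w[i] / hw else 1 / Nh
    } else {
      cur <- cur - 1 / (N - Nh)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  unname(best)
}

# one coverage_matrix row by direct per-bp averaging
oracle_coverage_row <- function(v, bs, mid, halfwidth, nbins, flip) {
  binw <- 2 * halfwidth / nbins
  row <- numeric(nbins)
  for (k in seq_len(nbins)) {
    s <- mid - halfwidth + (k - 1) * binw
    e <- s + binw
    row[k] <- oracle_window_mean(v, bs, s, e)$mean
  }
  if (flip) row <- rev(row)
  row
}

# risk ratio and Wald CI by direct arithmetic
oracle_risk_ratio <- function(a, na, b, nb) {
  rr <- (a / na) / (b / nb)
  se <- sqrt(1 / a - 1 / na + 1 / b - 1 / nb)
  c(rr, exp(log(rr) - 1.96 * se), exp(log(rr) + 1.96 * se))
}
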