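#' Parameters for signature extraction
#'
#' @param n_restarts independent random initializations (default 20);
#'   the restart with the lowest final KL divergence wins.
#' @param max_iter maximum multiplicative-update iterations (default
#'   2000).
#' @param tol relative KL change convergence threshold (default 1e-6).
#' @param seed RNG seed for the restarts.
#' @param pseudocount numerical floor added inside the updates
#'   (default 1e-12).
#' @return list of class `signature_params`.
#' @export
signature_params <- function(n_restarts = 20, max_iter = 2000, tol = 1e-6,
                             seed = 1, pseudocount = 1e-12) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  structure(list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 seed = seed, pseudocount = pseudocount),
            class = "signature_params")
}

# KL divergence D(V || WH), with the 0 log 0 = 0 convention
.kl_div <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

# one seeded NMF run; returns W, H, kl trace
.nmf_run <- function(V, k, max_iter, tol, eps) {
  nc <- nrow(V); ns <- ncol(V)
  W <- matrix(stats::runif(nc * k, 0.1, 1), nc, k)
  H <- matrix(stats::runif(k * ns, 0.1, 1) * mean(V) , k, ns)
  kl <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / outer(rep(1, nc), rowSums(H) + eps)
    WH <- W %*% H + eps
    d <- .kl_div(V, WH)
    kl <- c(kl, d)
    if (is.finite(prev) && abs(prev - d) <= tol * max(abs(prev), 1e-12)) {
      break
    }
    prev <- d
  }
  list(W = W, H = H, kl = kl)
}

# normalize signature columns to probability vectors, moving scale to H,
# and order signatures by decreasing total exposure
.normalize_model <- function(W, H) {
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- H * s
  ord <- order(-rowSums(H))
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- sprintf("S%d", seq_len(ncol(W)))
  list(W = W, H = H)
}

#' Extract mutational signatures by KL-divergence NMF
#'
#' Factorizes a non-negative channel-by-sample count matrix `V` into
#' `W %*% H` with `k` signatures using multiplicative Kullback-Leibler
#' updates (the Poisson-likelihood choice for counts). The best of
#' `n_restarts` seeded random initializations by final KL divergence is
#' returned, with `W` column-normalized to probability profiles and the
#' scale moved into the exposures `H`.
#'
#' @param V `context_matrix` or non-negative numeric matrix
#'   (channels x samples).
#' @param k number of signatures, `k < min(dim(V))`.
#' @param params a [signature_params()].
#' @return S3 object of class `signature_model`: `W` (channels x k,
#'   columns sum to 1), `H` (k x samples), `k`, `kl` (final divergence),
#'   `kl_trace`, `n_iterations`, `seed`, `dropped_samples`.
#' @export
nmf_extract <- function(V, k, params = signature_params()) {
  V <- unclass(V)
  attr(V, "kind") <- NULL
  if (any(V < 0)) stop("V must be non-negative")
  zero <- colSums(V) == 0
  dropped <- colnames(V)[zero]
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s) dropped", sum(zero)))
    V <- V[, !zero, drop = FALSE]
  }
  if (k >= min(dim(V))) stop("k must be smaller than both dimensions of V")
  set.seed(params$seed)
  best <- NULL
  for (r in seq_len(params$n_restarts)) {
    run <- .nmf_run(V, k, params$max_iter, params$tol, params$pseudocount)
    if (is.null(best) || utils::tail(run$kl, 1) < utils::tail(best$kl, 1)) {
      best <- run
    }
  }
  nm <- .normalize_model(best$W, best$H)
  rownames(nm$W) <- rownames(V)
  colnames(nm$H) <- colnames(V)
  structure(list(W = nm$W, H = nm$H, k = k,
                 kl = utils::tail(best$kl, 1), kl_trace = best$kl,
                 n_iterations = length(best$kl), seed = params$seed,
                 dropped_samples = dropped),
            class = "signature_model")
}

#' @method print signature_model
#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d signatures over %d channels, %d samples\n",
              x$k, nrow(x$W), ncol(x$H)))
  cat(sprintf("  final KL divergence %.6g after %d iterations (seed %d)\n",
              x$kl, x$n_iterations, x$seed))
  invisible(x)
}

#' @method fitted signature_model
#' @export
fitted.signature_model <- function(object, ...) object$W %*% object$H

#' @method coef signature_model
#' @export
coef.signature_model <- function(object, ...) object$W

#' Plot signature profiles
#'
#' @param x a `signature_model`.
#' @param ... passed to [graphics::barplot()].
#' @method plot signature_model
#' @export
plot.signature_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(x$k, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (s in seq_len(x$k)) {
    graphics::barplot(x$W[, s], names.arg = NA, ylab = colnames(x$W)[s], ...)
  }
  invisible(x)
}

# cosine similarity matrix between columns
.cosine_cols <- function(A, B = A) {
  An <- sweep(A, 2, sqrt(colSums(A^2)) + 1e-300, "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)) + 1e-300, "/")
  crossprod(An, Bn)
}

# mean silhouette width for labels under a distance matrix
.mean_silhouette <- function(d, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    sil[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sil)
}

#' Choose the number of signatures by restart stability
#'
#' For each candidate `k`, runs `n_restarts` factorizations, pools the
#' resulting signature profiles, clusters them into `k` groups
#' (average-linkage on cosine distance) and scores the mean silhouette
#' width; for `k = 1` the stability is the mean pairwise cosine
#' similarity of the restart profiles. The chosen `k` is the largest
#' whose stability reaches `stability_min` *and* whose clusters each
#' contain exactly one solution per restart (a reproducible rank);
#' if none qualifies, the most stable `k` wins.
#'
#' @param V channel-by-sample count matrix.
#' @param k_range integer vector of candidate `k`.
#' @param params a [signature_params()].
#' @param stability_min silhouette threshold (default 0.8).
#' @return list: `k` (chosen), `table` (per-k stability and mean KL),
#'   `models` (best model per k).
#' @export
select_k <- function(V, k_range, params = signature_params(),
                     stability_min = 0.8) {
  stopifnot(length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  rows <- list()
  models <- list()
  for (k in k_range) {
    set.seed(params$seed + k)
    runs <- lapply(seq_len(params$n_restarts), function(r) {
      .nmf_run(unclass(V), k, params$max_iter, params$tol,
               params$pseudocount)
    })
    kls <- vapply(runs, function(r) utils::tail(r$kl, 1), numeric(1))
    Ws <- lapply(runs, function(r) .normalize_model(r$W, r$H)$W)
    pool <- do.call(cbind, Ws)
    if (k == 1) {
      cs <- .cosine_cols(pool)
      stability <- if (ncol(pool) > 1) mean(cs[upper.tri(cs)]) else 1
      balanced <- TRUE
    } else {
      d <- 1 - .cosine_cols(pool)
      hc <- stats::hclust(stats::as.dist(d), method = "average")
      labels <- stats::cutree(hc, k = k)
      stability <- .mean_silhouette(d, labels)
      # a reproducible rank puts exactly one solution from every
      # restart into each cluster
      balanced <- all(table(labels) == params$n_restarts)
    }
    best <- which.min(kls)
    nm <- .normalize_model(runs[[best]]$W, runs[[best]]$H)
    rownames(nm$W) <- rownames(V); colnames(nm$H) <- colnames(V)
    models[[as.character(k)]] <- nm
    rows[[as.character(k)]] <- data.frame(k = k, stability = stability,
                                          balanced = balanced,
                                          mean_kl = mean(kls),
                                          best_kl = min(kls))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab$k[!is.na(tab$stability) & tab$stability >= stability_min &
                tab$balanced]
  chosen <- if (length(ok)) max(ok) else tab$k[which.max(tab$stability)]
  list(k = chosen, table = tab, models = models)
}

#' Refit per-sample signature probabilities against fixed profiles
#'
#' With `W` fixed and column-normalized, finds non-negative exposures
#' `h` per sample minimizing `KL(v || W h)` by H-only multiplicative
#' updates, then converts to per-channel posterior probabilities
#' `p(s | c) = W[c,s] h[s] / sum_s' W[c,s'] h[s']`.
#'
#' @param V channel-by-sample count matrix.
#' @param W channels x k column-normalized signature profiles.
#' @param params a [signature_params()].
#' @return object of class `assignment_probabilities`: list with
#'   `probs` (channels x k x samples array, each channel vector summing
#'   to 1) and `exposures` (k x samples).
#' @export
refit_probabilities <- function(V, W, params = signature_params()) {
  V <- unclass(V)
  k <- ncol(W)
  eps <- params$pseudocount
  H <- matrix(1, k, ncol(V), dimnames = list(colnames(W), colnames(V)))
  # scale initial exposures to the sample totals
  H <- sweep(H, 2, colSums(V) / k, "*")
  prev <- Inf
  for (it in seq_len(params$max_iter)) {
    WH <- W %*% H + eps
    H <- H * crossprod(W, V / WH) / (colSums(W) + eps)
    WH <- W %*% H + eps
    d <- .kl_div(V, WH)
    if (is.finite(prev) && abs(prev - d) <= params$tol * max(abs(prev), 1e-12)) break
    prev <- d
  }
  probs <- array(0, dim = c(nrow(W), k, ncol(V)),
                 dimnames = list(rownames(W), colnames(W), colnames(V)))
  fallback <- 0
  for (j in seq_len(ncol(V))) {
    num <- sweep(W, 2, H[, j], "*")
    den <- rowSums(num)
    bad <- den <= 0
    if (any(bad & V[, j] > 0)) fallback <- fallback + sum(bad & V[, j] > 0)
    p <- num / ifelse(den > 0, den, 1)
    p[bad, ] <- 1 / k
    probs[, , j] <- p
  }
  if (fallback > 0) {
    warning(sprintf(
      "%d channel(s) with zero model mass but nonzero counts; uniform fallback",
      fallback))
  }
  structure(list(probs = probs, exposures = H),
            class = "assignment_probabilities")
}

#' Assign each mutation a generating signature by multinomial sampling
#'
#' Draws, independently per mutation, a signature from the refit
#' posterior for that mutation's (sample, channel) pair.
#'
#' @param samples character vector of per-mutation sample ids.
#' @param channels character vector of per-mutation channel labels.
#' @param probabilities an [refit_probabilities()] result.
#' @param seed RNG seed.
#' @param expectation logical; TRUE returns the most probable signature
#'   deterministically instead of sampling.
#' @return character vector of signature labels.
#' @export
assign_mutations <- function(samples, channels, probabilities, seed = 1,
                             expectation = FALSE) {
  stopifnot(inherits(probabilities, "assignment_probabilities"))
  p <- probabilities$probs
  sig_names <- dimnames(p)[[2]]
  n <- length(samples)
  stopifnot(length(channels) == n)
  ok_s <- samples %in% dimnames(p)[[3]]
  ok_c <- channels %in% dimnames(p)[[1]]
  if (any(!ok_s | !ok_c)) {
    i <- which(!ok_s | !ok_c)[1]
    stop(sprintf("no probability vector for (sample '%s', channel '%s')",
                 samples[i], channels[i]))
  }
  out <- character(n)
  set.seed(seed)
  key <- paste(samples, channels, sep = "\r")
  for (g in split(seq_len(n), key)) {
    vec <- p[channels[g[1]], , samples[g[1]]]
    if (expectation) {
      out[g] <- sig_names[which.max(vec)]
    } else {
      out[g] <- sig_names[sample.int(length(vec), length(g),
                                     replace = TRUE, prob = vec)]
    }
  }
  out
}
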