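#' Fixed-bin genome-wide signal track
#'
#' A `signal_track` stores one numeric vector per chromosome at a fixed
#' bin size; `NA` marks uncovered bins. Bin `i` (1-based) covers base
#' offsets `[(i-1)*binsize, i*binsize)`.
#'
#' @param values named list of numeric vectors (one per chromosome).
#' @param binsize bin width in bp, `> 0`.
#' @param rfd logical; if TRUE the track is validated to lie in `[-1, 1]`.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(values, binsize, rfd = FALSE) {
  if (!is.list(values) ||
      (length(values) > 0 &&
       (is.null(names(values)) || any(names(values) == "")))) {
    stop("'values' must be a named list of per-chromosome numeric vectors")
  }
  binsize <- as.numeric(binsize)
  if (length(binsize) != 1 || is.na(binsize) || binsize <= 0) {
    stop("'binsize' must be a single positive number")
  }
  values <- lapply(values, as.numeric)
  if (rfd) {
    flat <- unlist(values, use.names = FALSE)
    flat <- flat[!is.na(flat)]
    if (length(flat) && (min(flat) < -1 - 1e-9 || max(flat) > 1 + 1e-9)) {
      stop("RFD-valued track must lie within [-1, 1]")
    }
  }
  structure(list(values = values, binsize = binsize),
            class = "signal_track")
}

#' @method print signal_track
#' @export
print.signal_track <- function(x, ...) {
  nb <- vapply(x$values, length, integer(1))
  cat(sprintf("signal_track: %d chromosome(s), binsize %g bp, %d bins\n",
              length(nb), x$binsize, sum(nb)))
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    cat(sprintf("  %s: %d bins, %.1f%% covered\n", ch, length(v),
                100 * mean(!is.na(v))))
  }
  invisible(x)
}

track_chroms <- function(x) names(x$values)

track_chrom_length <- function(x, chrom) length(x$values[[chrom]]) * x$binsize

# Closure computing the integrals of value*dx (NAs as 0) and covered bp
# from 0 to arbitrary positions x, clamped to the track extent. Used for
# exact length-weighted window means with partial-bin overlap.
.st_integrator <- function(v, bs) {
  n <- length(v)
  val <- ifelse(is.na(v), 0, v)
  cov <- as.numeric(!is.na(v))
  csv <- c(0, cumsum(val))
  csc <- c(0, cumsum(cov))
  function(x) {
    x <- pmin(pmax(x, 0), n * bs)
    i <- pmin(floor(x / bs), n)
    part <- x - i * bs
    j <- pmin(i + 1, n)
    vi <- ifelse(i < n, val[j], 0)
    ci <- ifelse(i < n, cov[j], 0)
    list(val = csv[i + 1] * bs + vi * part,
         cov = csc[i + 1] * bs + ci * part)
  }
}

#' Length-weighted window means over a signal track
#'
#' Computes, for each half-open window `[start, end)` on one chromosome,
#' the mean signal weighted by base-pair overlap with the track's bins,
#' ignoring missing bins, together with the covered fraction of the
#' window. Windows (or window parts) beyond the track extent count as
#' uncovered.
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param starts,ends numeric vectors of window bounds (bp, 0-based
#'   half-open).
#' @return data.frame with columns `mean` (NA where nothing is covered)
#'   and `covered_fraction`.
#' @export
track_window_means <- function(track, chrom, starts, ends) {
  stopifnot(inherits(track, "signal_track"), length(starts) == length(ends))
  if (any(ends <= starts)) stop("windows must satisfy start < end")
  v <- track$values[[chrom]]
  if (is.null(v)) {
    return(data.frame(mean = rep(NA_real_, length(starts)),
                      covered_fraction = 0))
  }
  I <- .st_integrator(v, track$binsize)
  a <- I(starts); b <- I(ends)
  cov_bp <- b$cov - a$cov
  m <- ifelse(cov_bp > 0, (b$val - a$val) / cov_bp, NA_real_)
  data.frame(mean = m, covered_fraction = cov_bp / (ends - starts))
}

# arithmetic on aligned tracks
.track_binop <- function(x, y, f) {
  if (x$binsize != y$binsize) stop("binsize mismatch between tracks")
  chroms <- union(track_chroms(x), track_chroms(y))
  if (!setequal(track_chroms(x), track_chroms(y))) {
    stop("chromosome sets differ between tracks")
  }
  vals <- lapply(chroms, function(ch) {
    a <- x$values[[ch]]; b <- y$values[[ch]]
    if (length(a) != length(b)) {
      n <- max(length(a), length(b))
      length(a) <- n; length(b) <- n
    }
    f(a, b)
  })
  names(vals) <- chroms
  signal_track(vals, x$binsize)
}
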