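#' Binned chromatin contact map
#'
#' Per-chromosome symmetric sparse matrices of non-negative contact
#' values at a fixed bin size (10 kb by default in this package's
#' analyses). Bin `i` (1-based) covers `[(i-1)*binsize, i*binsize)`.
#'
#' @param matrices named list of square symmetric `Matrix` sparse (or
#'   dense) matrices, one per chromosome.
#' @param binsize bin width in bp.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(matrices, binsize = 10000) {
  stopifnot(is.list(matrices))
  if (length(matrices) && is.null(names(matrices))) {
    stop("'matrices' must be named by chromosome")
  }
  matrices <- lapply(matrices, function(m) {
    if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
    m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
    if (nrow(m) != ncol(m)) stop("contact matrices must be square")
    if (length(m@x) && any(m@x < 0)) stop("contact values must be >= 0")
    if (!Matrix::isSymmetric(m, tol = 1e-8)) {
      stop("contact matrices must be symmetric")
    }
    m
  })
  structure(list(matrices = matrices, binsize = as.numeric(binsize)),
            class = "contact_map")
}

#' @method print contact_map
#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d chromosome(s), binsize %g bp\n",
              length(x$matrices), x$binsize))
  for (ch in names(x$matrices)) {
    m <- x$matrices[[ch]]
    cat(sprintf("  %s: %d x %d bins, %d stored contacts\n", ch,
                nrow(m), ncol(m), length(m@x)))
  }
  invisible(x)
}

#' Read a contact map from triplet text
#'
#' Rows are `chrom<TAB>bin_i<TAB>bin_j<TAB>value` with 0-based bin
#' indices; the map is symmetrized on read (each value stored at both
#' orientations).
#'
#' @param path triplet file path.
#' @param binsize bin width in bp (default 10000).
#' @param chrom_lengths optional named chromosome lengths (bp) fixing
#'   matrix dimensions; defaults to the largest bin index seen.
#' @return a [contact_map()].
#' @export
read_contacts <- function(path, binsize = 10000, chrom_lengths = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "i", "j", "value"),
                          stringsAsFactors = FALSE)
  if (any(df$value < 0)) stop(sprintf("negative contact value in %s", path))
  if (any(df$i < 0 | df$j < 0)) stop(sprintf("negative bin index in %s", path))
  chroms <- if (is.null(chrom_lengths)) unique(df$chrom) else names(chrom_lengths)
  mats <- lapply(chroms, function(ch) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    n <- if (is.null(chrom_lengths)) {
      max(sub$i, sub$j, 0) + 1
    } else {
      ceiling(chrom_lengths[[ch]] / binsize)
    }
    off <- sub$i != sub$j
    i <- c(sub$i, sub$j[off]) + 1L
    j <- c(sub$j, sub$i[off]) + 1L
    Matrix::sparseMatrix(i = i, j = j, x = c(sub$value, sub$value[off]),
                         dims = c(n, n))
  })
  names(mats) <- chroms
  contact_map(mats, binsize)
}

#' Write a contact map as triplet text (upper triangle)
#'
#' @param cmap a [contact_map()].
#' @param path output path.
#' @export
write_contacts <- function(cmap, path) {
  stopifnot(inherits(cmap, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cmap$matrices)) {
    m <- cmap$matrices[[ch]]
    tri <- Matrix::summary(Matrix::triu(m))
    tri <- tri[tri$x != 0, , drop = FALSE]
    tri <- tri[order(tri$i, tri$j), , drop = FALSE]
    if (nrow(tri)) {
      writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, tri$i - 1L, tri$j - 1L,
                         tri$x), con)
    }
  }
  invisible(path)
}

#' Merge replicate contact maps by summation
#'
#' @param ... two or more [contact_map()] objects with equal binsize.
#' @return the summed [contact_map()].
#' @export
merge_contacts <- function(...) {
  maps <- list(...)
  stopifnot(length(maps) >= 1)
  bs <- unique(vapply(maps, function(m) m$binsize, numeric(1)))
  if (length(bs) != 1) stop("binsize mismatch between contact maps")
  chroms <- unique(unlist(lapply(maps, function(m) names(m$matrices))))
  out <- lapply(chroms, function(ch) {
    parts <- Filter(Negate(is.null), lapply(maps, function(m) m$matrices[[ch]]))
    n <- max(vapply(parts, nrow, integer(1)))
    acc <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, n))
    for (p in parts) {
      if (nrow(p) < n) {
        big <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(n, n))
        big[seq_len(nrow(p)), seq_len(ncol(p))] <- p
        p <- big
      }
      acc <- acc + p
    }
    acc
  })
  names(out) <- chroms
  contact_map(out, bs)
}
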