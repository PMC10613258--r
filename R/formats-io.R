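#' Read a BED3/BED6 file into a validated interval frame
#'
#' Coordinates are kept in the native BED convention (0-based, half-open).
#' BED3 intervals receive `name = "."`, `score = 0`, `strand = "."`.
#'
#' @param path file path.
#' @param format `"BED6"` (default) or `"BED3"`.
#' @return interval data.frame (see [genomic_intervals()]), sorted.
#' @export
read_intervals <- function(path, format = c("BED6", "BED3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ncol_needed <- if (format == "BED3") 3L else 6L
  if (!length(lines)) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad)) {
    stop(sprintf("parse error in %s line %d: expected >= %d tab-separated fields, found %d",
                 path, bad[1], ncol_needed, nf[bad[1]]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("parse error in %s line %d: non-numeric coordinate",
                 path, bad[1]))
  }
  if (format == "BED6") {
    score <- suppressWarnings(as.numeric(get(5)))
    df <- data.frame(chrom = get(1), start = start, end = end,
                     name = get(4), score = score, strand = get(6),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = get(1), start = start, end = end,
                     name = ".", score = 0, strand = ".",
                     stringsAsFactors = FALSE)
  }
  validate_intervals(df, what = basename(path))
}

#' Write intervals as BED6
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  df <- intervals[, c("chrom", "start", "end", "name", "score", "strand")]
  df$score[is.na(df$score)] <- 0
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a fixed-bin signal track
#'
#' Records need not align to the bin grid: each record's value is
#' distributed into overlapping bins by base-pair overlap, so that
#' `sum(bin value * binsize)` equals `sum(record value * record length)`
#' (conservation). Bins with no overlapping record are missing (`NA`).
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param binsize target bin width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the maximum record end per chromosome.
#' @param rfd validate values in `[-1, 1]` (see [signal_track()]).
#' @return a [signal_track()].
#' @export
read_signal <- function(path, binsize, chrom_lengths = NULL, rfd = FALSE) {
  binsize <- as.numeric(binsize)
  if (length(binsize) != 1 || is.na(binsize) || binsize <= 0) {
    stop("'binsize' must be a single positive number")
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    vals <- lapply(chrom_lengths, function(L) {
      rep(NA_real_, ceiling(L / binsize))
    })
    if (is.null(chrom_lengths)) vals <- stats::setNames(list(), character(0))
    return(signal_track(vals, binsize, rfd = rfd))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4)
  if (length(bad)) {
    stop(sprintf("parse error in %s line %d: expected 4 tab-separated fields",
                 path, bad[1]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4)))
  bad <- which(is.na(s) | is.na(e) | is.na(v))
  if (length(bad)) {
    stop(sprintf("parse error in %s line %d: non-numeric field", path, bad[1]))
  }
  if (any(e <= s)) stop(sprintf("invalid record (end <= start) in %s", path))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(e, chrom, max)
  }
  vals <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    nb <- as.integer(ceiling(L / binsize))
    acc <- numeric(nb)
    covered <- numeric(nb)
    idx <- which(chrom == ch)
    if (length(idx)) {
      ord <- idx[order(s[idx])]
      if (any(s[ord][-1] < e[ord][-length(ord)])) {
        stop(sprintf("overlapping bedGraph records on %s in %s", ch, path))
      }
      for (r in ord) {
        b0 <- floor(s[r] / binsize) + 1
        b1 <- min(ceiling(e[r] / binsize), nb)
        if (b0 > nb) next
        bins <- b0:b1
        ov <- pmin(e[r], bins * binsize) - pmax(s[r], (bins - 1) * binsize)
        acc[bins] <- acc[bins] + v[r] * ov
        covered[bins] <- covered[bins] + ov
      }
    }
    out <- acc / binsize
    out[covered == 0] <- NA_real_
    vals[[ch]] <- out
  }
  signal_track(vals, binsize, rfd = rfd)
}

#' Write a signal track as bedGraph
#'
#' Consecutive bins with identical values are merged into one record;
#' missing bins are omitted.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_signal <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$binsize
  for (ch in track_chroms(track)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(ifelse(is.na(v), "NA", sprintf("%.17g", v)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (!any(keep)) next
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s", ch, starts[keep] * bs,
                       ends[keep] * bs, r$values[keep]), con)
  }
  invisible(path)
}

.functional_classes <- c("frameshift", "missense", "nonsense",
                         "synonymous", "noncoding", "other")

# infer SNV/INS/DEL from allele lengths; NA for unclassifiable
.infer_mut_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
    ifelse(nchar(alt) > nchar(ref), "INS",
      ifelse(nchar(ref) > nchar(alt), "DEL", NA_character_)))
}

#' Read a COSMIC-like somatic mutation table
#'
#' Expects a tab-separated file with a header naming at least
#' `sample, chrom, pos, ref, alt, functional_class`; optional columns
#' `gene` and `mut_class`. Positions are 1-based (VCF convention); a
#' 0-based `start` column is added on read, the single conversion point
#' in the package. `mut_class` is inferred from allele lengths when
#' absent. Multi-allelic records (comma in `alt`) and multi-nucleotide
#' substitutions (`|ref| == |alt| > 1`) are dropped with a warning.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample, chrom, pos, start, ref, alt,
#'   mut_class, functional_class, gene`. Duplicate rows are preserved.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("sample", "chrom", "pos", "ref", "alt", "functional_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("mutation table %s lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  if (any(is.na(df$pos) | df$pos < 1)) {
    stop(sprintf("mutation table %s has invalid positions (need pos >= 1)", path))
  }
  bad <- !df$functional_class %in% .functional_classes
  if (any(bad)) {
    stop(sprintf(
      "unknown functional_class '%s' in %s; accepted tokens: %s",
      df$functional_class[which(bad)[1]], path,
      paste(.functional_classes, collapse = ", ")))
  }
  multi <- grepl(",", df$alt, fixed = TRUE) |
    (nchar(df$ref) == nchar(df$alt) & nchar(df$ref) > 1)
  if (any(multi)) {
    warning(sprintf("%d multi-allelic/MNV record(s) dropped from %s",
                    sum(multi), path))
    df <- df[!multi, , drop = FALSE]
  }
  inferred <- .infer_mut_class(df$ref, df$alt)
  if ("mut_class" %in% names(df)) {
    df$mut_class <- as.character(df$mut_class)
    mismatch <- !is.na(inferred) & df$mut_class != inferred
    if (any(mismatch)) {
      stop(sprintf("mut_class inconsistent with allele lengths at %s row %d",
                   path, which(mismatch)[1]))
    }
  } else {
    df$mut_class <- inferred
  }
  df$start <- df$pos - 1
  rownames(df) <- NULL
  df[, c("sample", "chrom", "pos", "start", "ref", "alt", "mut_class",
         "functional_class", "gene")]
}

#' Write a mutation table in the package's TSV dialect
#'
#' @param mutations data.frame as returned by [read_mutations()].
#' @param path output path.
#' @export
write_mutations <- function(mutations, path) {
  cols <- c("sample", "chrom", "pos", "ref", "alt", "mut_class",
            "functional_class", "gene")
  utils::write.table(mutations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Convert a mutation table to BED intervals of the mutated positions
#'
#' Each record becomes a 1-bp interval at its 0-based start position.
#'
#' @param mutations mutation data.frame.
#' @return interval data.frame.
#' @export
mutations_to_intervals <- function(mutations) {
  genomic_intervals(mutations$chrom, mutations$start, mutations$start + 1,
                    name = mutations$sample)
}

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate FASTA header '%s' in %s",
                 nm[anyDuplicated(nm)], path))
  }
  if (any(Biostrings::width(set) == 0)) {
    stop(sprintf("empty FASTA record in %s", path))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_sequence <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
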