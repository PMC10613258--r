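.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(.COMP[strsplit(x, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical SBS96 channel labels
#'
#' Ordered substitution-major: `C>A, C>G, C>T, T>A, T>C, T>G`, then 5'
#' flank and 3' flank each in `A, C, G, T` order.
#'
#' @return character vector of 96 labels like `"A[C>T]A"`.
#' @export
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    for (l in .BASES) for (r in .BASES) {
      out <- c(out, sprintf("%s[%s]%s", l, s, r))
    }
  }
  out
}

#' SBS96 channel of a single-base substitution
#'
#' Purine-centered substitutions are reverse-complemented into the
#' pyrimidine frame. Vectorized.
#'
#' @param ref_trinucleotide 3-character reference context centered on
#'   the mutated base.
#' @param alt_base substituted base.
#' @return channel label (`"A[C>T]A"` style) or `NA` when
#'   unclassifiable (N in context, or alt equal to the central base).
#' @export
sbs96_channel <- function(ref_trinucleotide, alt_base) {
  tri <- toupper(ref_trinucleotide)
  alt <- toupper(alt_base)
  n <- max(length(tri), length(alt))
  tri <- rep_len(tri, n); alt <- rep_len(alt, n)
  out <- rep(NA_character_, n)
  ok <- nchar(tri) == 3 & grepl("^[ACGT]{3}$", tri) & alt %in% .BASES
  if (!any(ok)) return(out)
  ctr <- substr(tri, 2, 2)
  ok <- ok & ctr != alt
  pur <- ok & ctr %in% c("A", "G")
  tri[pur] <- .revcomp(tri[pur])
  alt[pur] <- .COMP[alt[pur]]
  ctr <- substr(tri, 2, 2)
  out[ok] <- sprintf("%s[%s>%s]%s", substr(tri[ok], 1, 1), ctr[ok],
                     alt[ok], substr(tri[ok], 3, 3))
  out
}

# per-mutation SBS96 channel from a reference genome; NA outside
# classifiable contexts. Checks the recorded ref allele.
.snv_channels <- function(snvs, genome) {
  n <- nrow(snvs)
  chan <- rep(NA_character_, n)
  mismatch <- logical(n)
  for (ch in unique(snvs$chrom)) {
    seq <- genome[[ch]]
    if (is.null(seq)) stop(sprintf("chromosome '%s' absent from genome", ch))
    idx <- which(snvs$chrom == ch)
    pos <- snvs$pos[idx]
    if (any(pos > nchar(seq))) stop("mutation position outside sequence")
    ref_here <- substr(rep(seq, length(idx)), pos, pos)
    mismatch[idx] <- ref_here != snvs$ref[idx]
    inner <- pos > 1 & pos < nchar(seq)
    tri <- rep(NA_character_, length(idx))
    tri[inner] <- substr(rep(seq, sum(inner)), pos[inner] - 1, pos[inner] + 1)
    chan[idx] <- ifelse(mismatch[idx] | !inner, NA_character_,
                        sbs96_channel(tri, snvs$alt[idx]))
  }
  list(channel = chan, mismatch = mismatch)
}

#' SBS96 context matrix from SNVs and a reference genome
#'
#' @param snvs mutation data.frame (non-SNV rows are ignored).
#' @param genome named character vector from [read_sequence()].
#' @param samples optional sample universe fixing column order.
#' @return 96 x samples integer `context_matrix` (attribute
#'   `kind = "SBS96"`); attributes `rejected` (reference-mismatch count)
#'   and `unclassifiable` report dropped records.
#' @export
build_sbs96 <- function(snvs, genome, samples = NULL) {
  snvs <- snvs[snvs$mut_class == "SNV", , drop = FALSE]
  res <- if (nrow(snvs)) .snv_channels(snvs, genome) else
    list(channel = character(0), mismatch = logical(0))
  if (any(res$mismatch)) {
    warning(sprintf("%d SNV(s) rejected: recorded ref differs from genome",
                    sum(res$mismatch)))
  }
  if (is.null(samples)) samples <- sort(unique(snvs$sample))
  keep <- !is.na(res$channel)
  m <- table(factor(res$channel[keep], levels = sbs96_labels()),
             factor(snvs$sample[keep], levels = samples))
  m <- matrix(as.integer(m), nrow = 96,
              dimnames = list(sbs96_labels(), samples))
  structure(m, kind = "SBS96",
            rejected = sum(res$mismatch),
            unclassifiable = sum(!keep & !res$mismatch),
            class = c("context_matrix", "matrix"))
}

#' Canonical ID83 channel labels
#'
#' SigProfiler raw naming: `length:type:base-or-class:subscript`, with
#' 1-bp events sub-classified by pyrimidine-collapsed base and
#' homopolymer context, longer events by adjacent tandem-repeat copies
#' (`R`) and repeat-free deletions by microhomology length (`M`).
#'
#' @return character vector of 83 labels.
#' @export
id83_labels <- function() {
  out <- character(0)
  for (ty in c("Del", "Ins")) {
    for (b in c("C", "T")) {
      out <- c(out, sprintf("1:%s:%s:%d", ty, b, 0:5))
    }
  }
  for (ty in c("Del", "Ins")) {
    for (L in 2:5) out <- c(out, sprintf("%d:%s:R:%d", L, ty, 0:5))
  }
  mh <- list(`2` = 1, `3` = 1:2, `4` = 1:3, `5` = 1:5)
  for (L in names(mh)) {
    out <- c(out, sprintf("%s:Del:M:%d", L, mh[[L]]))
  }
  out
}

# left-align an indel: anchor p (1-based, may become 0), event sequence S
# placed immediately right of the anchor. Returns list(p, s).
.left_align <- function(seq, p, s) {
  L <- nchar(s)
  while (p >= 1 && substr(seq, p, p) == substr(s, L, L)) {
    s <- paste0(substr(seq, p, p), substr(s, 1, L - 1))
    p <- p - 1
  }
  list(p = p, s = s)
}

# count adjacent exact copies of s in seq starting at position from
.count_copies <- function(seq, from, s) {
  L <- nchar(s)
  n <- 0
  while (from + L - 1 <= nchar(seq) && substr(seq, from, from + L - 1) == s) {
    n <- n + 1
    from <- from + L
  }
  n
}

#' ID83 channel of one insertion or deletion
#'
#' The indel is left-aligned first. 1-bp events are classified by
#' pyrimidine-collapsed base and homopolymer run length (deletions:
#' run length including the deleted base, minus one, capped at 5;
#' insertions: pre-existing run length, capped at 5). Longer events are
#' classified by the number of additional adjacent tandem copies of the
#' indel sequence (capped at 5); repeat-free deletions with flanking
#' microhomology get `M` channels (`min(mh, 5)`).
#'
#' @param mutation one-row mutation data.frame (`mut_class` INS or DEL,
#'   VCF-style anchored alleles).
#' @param genome named character vector of reference sequences.
#' @return an [id83_labels()] label, or `NA` when unclassifiable.
#' @export
id83_channel <- function(mutation, genome) {
  cls <- mutation$mut_class[1]
  if (!cls %in% c("INS", "DEL")) stop("mut_class must be INS or DEL")
  seq <- genome[[mutation$chrom[1]]]
  if (is.null(seq)) stop(sprintf("chromosome '%s' absent from genome",
                                 mutation$chrom[1]))
  ref <- mutation$ref[1]; alt <- mutation$alt[1]
  if (substr(ref, 1, 1) != substr(alt, 1, 1)) return(NA_character_)
  p <- mutation$pos[1]             # anchor base (shared first base)
  s <- if (cls == "DEL") substr(ref, 2, nchar(ref)) else
    substr(alt, 2, nchar(alt))
  if (!grepl("^[ACGT]+$", s)) return(NA_character_)
  la <- .left_align(seq, p, s)
  p <- la$p; s <- la$s
  L <- nchar(s)
  Lb <- min(L, 5)
  if (L == 1) {
    base <- if (s %in% c("A", "G")) .COMP[[s]] else s
    if (cls == "DEL") {
      # run containing the deleted base: deleted base + copies after it
      run <- 1 + .count_copies(seq, p + 2, s)
      sub <- min(run - 1, 5)
    } else {
      run <- .count_copies(seq, p + 1, s)
      sub <- min(run, 5)
    }
    return(sprintf("1:%s:%s:%d", .id_type(cls == "DEL"), base, sub))
  }
  if (cls == "DEL") {
    copies <- .count_copies(seq, p + 1 + L, s)
    if (copies > 0) {
      return(sprintf("%d:Del:R:%d", Lb, min(copies, 5)))
    }
    # microhomology: prefix of s vs sequence after the deletion, and
    # suffix of s vs sequence before it
    after <- substr(seq, p + 1 + L, min(nchar(seq), p + 2 * L))
    mh_f <- 0
    while (mh_f < L - 1 && mh_f < nchar(after) &&
           substr(s, mh_f + 1, mh_f + 1) ==
             substr(after, mh_f + 1, mh_f + 1)) {
      mh_f <- mh_f + 1
    }
    mh_b <- 0
    while (mh_b < L - 1 && p - mh_b >= 1 &&
           substr(s, L - mh_b, L - mh_b) ==
             substr(seq, p - mh_b, p - mh_b)) {
      mh_b <- mh_b + 1
    }
    mh <- max(mh_f, mh_b)
    if (mh >= 1) return(sprintf("%d:Del:M:%d", Lb, min(mh, 5)))
    return(sprintf("%d:Del:R:0", Lb))
  }
  copies <- .count_copies(seq, p + 1, s)
  sprintf("%d:Ins:R:%d", Lb, min(copies, 5))
}

.id_type <- function(is_del) if (is_del) "Del" else "Ins"

#' ID83 context matrix from indels and a reference genome
#'
#' @param indels mutation data.frame (non-indel rows ignored).
#' @param genome named character vector from [read_sequence()].
#' @param samples optional sample universe fixing column order.
#' @return 83 x samples integer `context_matrix` (`kind = "ID83"`),
#'   attribute `unclassifiable` counting dropped records.
#' @export
build_id83 <- function(indels, genome, samples = NULL) {
  indels <- indels[indels$mut_class %in% c("INS", "DEL"), , drop = FALSE]
  chan <- vapply(seq_len(nrow(indels)), function(i) {
    id83_channel(indels[i, , drop = FALSE], genome)
  }, character(1))
  if (is.null(samples)) samples <- sort(unique(indels$sample))
  keep <- !is.na(chan)
  m <- table(factor(chan[keep], levels = id83_labels()),
             factor(indels$sample[keep], levels = samples))
  m <- matrix(as.integer(m), nrow = 83,
              dimnames = list(id83_labels(), samples))
  structure(m, kind = "ID83", unclassifiable = sum(!keep),
            class = c("context_matrix", "matrix"))
}

#' Per-mutation context channels
#'
#' SBS96 channels for SNVs, ID83 channels for indels; `NA` where
#' unclassifiable.
#'
#' @param mutations mutation data.frame.
#' @param genome named character vector of reference sequences.
#' @return character vector aligned with `mutations` rows.
#' @export
mutation_channels <- function(mutations, genome) {
  out <- rep(NA_character_, nrow(mutations))
  is_snv <- mutations$mut_class == "SNV"
  if (any(is_snv)) {
    res <- .snv_channels(mutations[is_snv, , drop = FALSE], genome)
    out[is_snv] <- res$channel
  }
  idx <- which(!is_snv)
  for (i in idx) {
    out[i] <- id83_channel(mutations[i, , drop = FALSE], genome)
  }
  out
}
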