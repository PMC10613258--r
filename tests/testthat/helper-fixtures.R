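# shared in-code fixtures

# small deterministic bundle reused by several suites (no mutations)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 42, chrom_lengths = c(chrA = 1.2e6, chrB = 1.2e6),
        n_genes = 60, origin_spacing = 100000, terminus_width = 20000,
        edge_margin = 6e4,
        tumor_specs = list(n_tumors = 0))
      cache <<- simulate_genome(cfg)
    }
    cache
  }
})

# one-line BED6 writer for parse tests
write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny deterministic mutation frame helper
make_mut <- function(sample, chrom, pos, ref, alt, functional = "noncoding",
                     gene = NA_character_) {
  data.frame(sample = sample, chrom = chrom, pos = pos, start = pos - 1,
             ref = ref, alt = alt,
             mut_class = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                                ifelse(nchar(alt) > nchar(ref), "INS", "DEL")),
             functional_class = functional, gene = gene,
             stringsAsFactors = FALSE)
}

# straightforward slow re-implementation of the ID83 rules, used as a
# dual-implementation oracle for the classifier
oracle_id83 <- function(seq, pos, ref, alt) {
  is_del <- nchar(ref) > nchar(alt)
  s <- if (is_del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  p <- pos
  # left-align
  repeat {
    L <- nchar(s)
    if (p < 1 || substr(seq, p, p) != substr(s, L, L)) break
    s <- paste0(substr(seq, p, p), substr(s, 1, L - 1))
    p <- p - 1
  }
  L <- nchar(s)
  count_right <- function(from) {
    n <- 0
    while (from + L - 1 <= nchar(seq) &&
           substr(seq, from, from + L - 1) == s) {
      n <- n + 1; from <- from + L
    }
    n
  }
  if (L == 1) {
    base <- c(A = "T", C = "C", G = "C", T = "T")[[s]]
    if (is_del) {
      run <- 1 + count_right(p + 2)
      return(sprintf("1:Del:%s:%d", base, min(run - 1, 5)))
    }
    run <- count_right(p + 1)
    return(sprintf("1:Ins:%s:%d", base, min(run, 5)))
  }
  Lb <- min(L, 5)
  if (!is_del) {
    return(sprintf("%d:Ins:R:%d", Lb, min(count_right(p + 1), 5)))
  }
  copies <- count_right(p + 1 + L)
  if (copies > 0) return(sprintf("%d:Del:R:%d", Lb, min(copies, 5)))
  mh <- 0
  for (m in seq_len(L - 1)) {
    if (p + L + m <= nchar(seq) &&
        substr(s, 1, m) == substr(seq, p + L + 1, p + L + m)) mh <- max(mh, m)
    if (p - m + 1 >= 1 &&
        substr(s, L - m + 1, L) == substr(seq, p - m + 1, p)) mh <- max(mh, m)
  }
  if (mh >= 1) return(sprintf("%d:Del:M:%d", Lb, min(mh, 5)))
  sprintf("%d:Del:R:0", Lb)
}
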