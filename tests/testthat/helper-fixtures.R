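# Small fixture builders shared across test files.

# genotype matrix from strings like "HHAHH" (H = heterozygous 1,
# A = homozygous 0, "." = missing); one string per individual
gm <- function(..., pos = NULL, chrom = "2") {
  rows <- c(...)
  m <- t(vapply(strsplit(rows, ""), function(ch) {
    out <- rep(NA_integer_, length(ch))
    out[ch == "H"] <- 1L
    out[ch == "A"] <- 0L
    out
  }, integer(nchar(rows[1L]))))
  k <- ncol(m)
  if (is.null(pos)) pos <- seq_len(k) * 1e5
  genotype_matrix(m, marker_map(chrom, paste0("m", seq_len(k)), pos))
}

# independent naive crossover scan: per individual, walk the non-missing
# calls and tally flips; adjacent-pair flips per interval, skipped-missing
# flips counted separately
naive_crossovers <- function(g) {
  m <- unclass(g)
  k <- ncol(m) - 1L
  events <- integer(k)
  merged <- 0L
  per_ind <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    idx <- which(!is.na(m[i, ]))
    if (length(idx) < 2L) next
    for (t in seq_len(length(idx) - 1L)) {
      a <- idx[t]; b <- idx[t + 1L]
      if (m[i, a] != m[i, b]) {
        per_ind[i] <- per_ind[i] + 1L
        if (b == a + 1L) events[a] <- events[a] + 1L else merged <- merged + 1L
      }
    }
  }
  list(events = events, merged = merged, per_individual = per_ind)
}

# random genotype matrix with optional missingness (values already in
# {0, 1, NA}; not necessarily biologically coherent - used as scan input)
random_gm <- function(n, m, miss = 0.1) {
  x <- matrix(sample(c(0L, 1L), n * m, replace = TRUE), n, m)
  x[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  genotype_matrix(x, marker_map("2", paste0("m", seq_len(m)), seq_len(m) * 1e5))
}

# toy coding region: returns list(aln, cds) with a single plus-strand gene
# whose codons are known; extra flanking non-coding bases on each side
toy_gene_region <- function(codons = c("ATG", "GCT", "GGC", "CTA", "TAA"),
                            flank = "ACGTAC", strand = "+", nsamp = 4) {
  cds_seq <- paste(codons, collapse = "")
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    cds_seq <- paste(rev(comp[strsplit(cds_seq, "")[[1L]]]), collapse = "")
  }
  ref <- paste0(flank, cds_seq, flank)
  aln <- rep(ref, nsamp)
  cds <- data.frame(start = nchar(flank) + 1L,
                    end = nchar(flank) + nchar(cds_seq),
                    strand = strand, frame = 0L, gene = "g1",
                    stringsAsFactors = FALSE)
  list(aln = aln, cds = cds, ref = ref)
}

# mutate one sample of a character-vector alignment at position pos
mutate_at <- function(aln, sample, pos, base) {
  s <- strsplit(aln[sample], "")[[1L]]
  s[pos] <- base
  aln[sample] <- paste(s, collapse = "")
  aln
}
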