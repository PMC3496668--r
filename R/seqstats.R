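## alignment handling: accept a Biostrings::DNAStringSet or a character
## vector of equal-length sequences; work internally on a samples x sites
## character matrix
aln_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    return(toupper(x))
  }
  if (length(x) == 0L) return(matrix(character(0), 0L, 0L))
  if (inherits(x, "DNAStringSet")) {
    if (length(unique(Biostrings::width(x))) != 1L)
      stop("aligned sequences must have equal length")
    return(t(vapply(as.character(x),
                    function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                    character(Biostrings::width(x)[1L]))))
  }
  x <- toupper(as.character(x))
  if (length(unique(nchar(x))) != 1L)
    stop("aligned sequences must have equal length")
  t(vapply(x, function(s) strsplit(s, "", fixed = TRUE)[[1L]],
           character(nchar(x[1L]))))
}

fourfold_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1L, 2L))
  pre[vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1L))]
}

#' Default codon preference table
#'
#' Major-codon preferences for the *D. pseudoobscura* species group, as
#' shipped in `inst/extdata/codon_preference_dpse.tsv`: for each amino
#' acid one preferred (major) codon, C- or G-ending as is typical of
#' *Drosophila* translational selection. The table is a swappable default:
#' any data frame with columns `codon` and `preferred` can be passed to
#' [classify_sites()] in its place.
#'
#' @return Data frame with columns `codon`, `aa`, `preferred`.
#' @export
default_preference_table <- function() {
  path <- system.file("extdata", "codon_preference_dpse.tsv",
                      package = "recmapsel", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  out <- comp[x]
  out[is.na(out)] <- "N"
  rev(unname(out))
}

#' Classify coding sites by degeneracy and codon preference
#'
#' Walks every annotated CDS on the reference sample (the first sequence),
#' assembles codons strand- and frame-aware, and flags the third positions
#' of 4-fold degenerate codon families. A site's unpreferred status comes
#' from the preference table keyed by the codon observed in the reference
#' sample. Sites covered by more than one CDS segment (overlapping reading
#' frames) are never eligible, and genes with an internal stop codon are
#' excluded and logged.
#'
#' @param aln alignment (`DNAStringSet` or character vector); sequence 1 is
#'   the reference sample.
#' @param cds data frame of CDS segments with columns `start`, `end`
#'   (1-based, within alignment coordinates), `strand` (`"+"`/`"-"`),
#'   `frame` (0/1/2 bases to skip), `gene`.
#' @param preference codon preference table (columns `codon`, `preferred`);
#'   defaults to the shipped *D. pseudoobscura*-group table.
#' @return Data frame with one row per alignment column: `pos`, `coding`
#'   (covered by >= 1 CDS), `multi_frame`, `fourfold`, `codon`,
#'   `unpreferred`. Attribute `"excluded_genes"` lists genes dropped for
#'   internal stops.
#' @export
classify_sites <- function(aln, cds, preference = default_preference_table()) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  ref <- m[1L, ]
  stopifnot(all(c("start", "end", "strand", "frame", "gene") %in% names(cds)))
  if (any(cds$start < 1L | cds$end > L)) stop("CDS segment outside sequence bounds")
  if (!all(cds$frame %in% 0:2)) stop("frame must be 0, 1 or 2")
  cover <- integer(L)
  for (k in seq_len(nrow(cds)))
    cover[cds$start[k]:cds$end[k]] <- cover[cds$start[k]:cds$end[k]] + 1L
  fourfold <- logical(L)
  codon_at <- rep(NA_character_, L)
  ff_pre <- fourfold_prefixes()
  gcode <- Biostrings::GENETIC_CODE
  pref <- setNames(as.logical(preference$preferred), preference$codon)
  excluded <- character(0)
  for (g in unique(cds$gene)) {
    seg <- cds[cds$gene == g, , drop = FALSE]
    minus <- seg$strand[1L] == "-"
    seg <- seg[order(seg$start, decreasing = minus), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      p <- seg$start[k]:seg$end[k]
      if (minus) rev(p) else p
    }))
    frame <- seg$frame[1L]
    if (frame > 0L) pos <- pos[-seq_len(frame)]
    ncod <- length(pos) %/% 3L
    if (ncod == 0L) next
    pos <- pos[seq_len(3L * ncod)]
    bases <- ref[pos]
    if (minus) bases <- vapply(bases, function(b)
      c(A = "T", C = "G", G = "C", T = "A")[b], character(1L))
    bases[is.na(bases) | !bases %in% c("A", "C", "G", "T")] <- "N"
    cod <- paste0(bases[seq(1L, by = 3L, length.out = ncod)],
                  bases[seq(2L, by = 3L, length.out = ncod)],
                  bases[seq(3L, by = 3L, length.out = ncod)])
    aa <- gcode[cod]
    if (any(aa[-length(aa)] == "*", na.rm = TRUE)) {
      excluded <- c(excluded, g)
      next
    }
    is4 <- substr(cod, 1L, 2L) %in% ff_pre & !grepl("N", cod, fixed = TRUE)
    third <- pos[seq(3L, by = 3L, length.out = ncod)]
    fourfold[third[is4]] <- TRUE
    codon_at[third[is4]] <- cod[is4]
  }
  multi <- cover > 1L
  fourfold[multi] <- FALSE
  out <- data.frame(pos = seq_len(L), coding = cover > 0L,
                    multi_frame = multi, fourfold = fourfold,
                    codon = codon_at,
                    unpreferred = ifelse(is.na(codon_at), NA,
                                         !pref[codon_at]),
                    stringsAsFactors = FALSE)
  attr(out, "excluded_genes") <- excluded
  out
}

#' Eligible-site mask
#'
#' A site is eligible when every sample carries an unambiguous A/C/G/T call
#' at it and it is classified 4-fold degenerate (and, for the
#' `"unpreferred"` stream, sits in an unpreferred reference codon). Read
#' depth and base-quality filtering are assumed to have happened upstream,
#' encoded as ambiguity/missing characters in the alignment.
#'
#' @param aln alignment (`DNAStringSet` or character vector).
#' @param classification output of [classify_sites()], or `NULL` to apply
#'   only the complete-call rule.
#' @param stream `"unpreferred"` (default) or `"all4fold"`.
#' @return Logical vector, one flag per alignment column.
#' @export
eligible_mask <- function(aln, classification = NULL,
                          stream = c("unpreferred", "all4fold")) {
  stream <- match.arg(stream)
  m <- aln_matrix(aln)
  ok <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
  if (!is.null(classification)) {
    ok <- ok & classification$fourfold
    if (stream == "unpreferred")
      ok <- ok & !is.na(classification$unpreferred) & classification$unpreferred
  }
  ok
}

site_pair_diff <- function(m) {
  # per column: fraction of sequence pairs that differ
  n <- nrow(m)
  apply(m, 2L, function(col) {
    cnt <- table(col)
    1 - sum(choose(cnt, 2L)) / choose(n, 2L)
  })
}

#' Average pairwise nucleotide diversity
#'
#' Per eligible site, the fraction of sequence pairs that differ; the
#' aggregate is the mean over eligible sites. At a biallelic site with
#' allele counts `(i, n - i)` the per-site value is
#' `i * (n - i) / choose(n, 2)`.
#'
#' @param aln alignment with at least 2 sequences.
#' @param eligible logical site mask (default: all sites).
#' @return List with `per_site` (named by position), `mean`, `n_sites`.
#' @export
pairwise_diversity <- function(aln, eligible = NULL) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  if (is.null(eligible)) eligible <- rep(TRUE, ncol(m))
  idx <- which(eligible)
  ps <- site_pair_diff(m[, idx, drop = FALSE])
  list(per_site = setNames(ps, idx), mean = mean(ps), n_sites = length(idx))
}

#' Polymorphic- and eligible-site counts
#'
#' A site is polymorphic when at least two distinct states segregate among
#' the samples. The `(polymorphic, eligible)` pair is the two-column
#' response bound together for the binomial/quasibinomial GLMs (the count
#' of SNP bases against non-SNP eligible bases).
#'
#' @inheritParams pairwise_diversity
#' @return Named integer vector `c(polymorphic, eligible)`.
#' @export
polymorphic_fraction <- function(aln, eligible = NULL) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  if (is.null(eligible)) eligible <- rep(TRUE, ncol(m))
  sub <- m[, eligible, drop = FALSE]
  poly <- apply(sub, 2L, function(col) length(unique(col)) >= 2L)
  c(polymorphic = sum(poly), eligible = ncol(sub))
}

#' Average pairwise between-species divergence
#'
#' Mean over all cross-species sequence pairs of the per-site difference
#' fraction at eligible sites.
#'
#' @param aln_a,aln_b alignments of the two species' samples over the same
#'   columns (>= 1 sequence each).
#' @param eligible logical site mask.
#' @return List with `per_site`, `mean`, `n_sites`.
#' @export
pairwise_divergence <- function(aln_a, aln_b, eligible = NULL) {
  ma <- aln_matrix(aln_a); mb <- aln_matrix(aln_b)
  if (nrow(ma) < 1L || nrow(mb) < 1L) stop("need at least 1 sequence per species")
  if (ncol(ma) != ncol(mb)) stop("alignments must share columns")
  if (is.null(eligible)) eligible <- rep(TRUE, ncol(ma))
  idx <- which(eligible)
  ps <- vapply(idx, function(j) {
    ca <- table(ma[, j]); cb <- table(mb[, j])
    shared <- intersect(names(ca), names(cb))
    1 - sum(ca[shared] * cb[shared]) / (nrow(ma) * nrow(mb))
  }, numeric(1L))
  list(per_site = setNames(ps, idx), mean = mean(ps), n_sites = length(idx))
}

#' GC content of a sequence span
#'
#' @param seq single sequence (character or `DNAStringSet` element).
#' @param start,end 1-based span bounds (default: whole sequence).
#' @return Proportion of G or C among unambiguous bases.
#' @export
gc_content <- function(seq, start = 1L, end = NULL) {
  s <- aln_matrix(if (length(seq) > 1L) seq[1L] else seq)[1L, ]
  if (is.null(end)) end <- length(s)
  if (end < start) stop("zero-length interval")
  s <- s[start:end]
  s <- s[s %in% c("A", "C", "G", "T")]
  if (!length(s)) return(NA_real_)
  mean(s %in% c("G", "C"))
}

cds_union_bp <- function(cds, start, end) {
  s <- pmax(cds$start, start); e <- pmin(cds$end, end)
  keep <- s <= e
  if (!any(keep)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(s[keep], e[keep]))
  sum(IRanges::width(ir))
}

#' Gene density of an interval
#'
#' Proportion of nucleotides within the interval that are coding
#' (overlapping CDS segments counted once, as their union).
#'
#' @param cds CDS data frame (`start`, `end`, 1-based inclusive).
#' @param start,end interval bounds (1-based inclusive).
#' @return Proportion in `[0, 1]`.
#' @export
gene_density_interval <- function(cds, start, end) {
  if (end < start) stop("zero-length interval")
  cds_union_bp(cds, start, end) / (end - start + 1L)
}

#' Gene density around a gene's midpoint
#'
#' Proportion of coding bases within `flank` bp on either side of the
#' midpoint, truncating (and flagging) at chromosome ends.
#'
#' @param midpoint gene midpoint (bp).
#' @param cds CDS data frame.
#' @param flank half-window in bp (default 50 kb).
#' @param chrom_len chromosome length for truncation.
#' @return Proportion, with attribute `"truncated"` when the window hit a
#'   chromosome end.
#' @export
gene_density_flank <- function(midpoint, cds, flank = 50000L, chrom_len = Inf) {
  lo <- max(1L, midpoint - flank)
  hi <- min(chrom_len, midpoint + flank)
  out <- cds_union_bp(cds, lo, hi) / (hi - lo + 1L)
  attr(out, "truncated") <- (lo > midpoint - flank) || (hi < midpoint + flank)
  out
}

#' Per-interval diversity, divergence and covariate summaries
#'
#' Builds the interval-level table behind the diversity/divergence models:
#' for each physical interval, counts of polymorphic and eligible 4-fold
#' (unpreferred-codon) sites among the focal species' samples, the
#' between-species divergence count over the same stream, GC content and
#' gene density of the interval, and the neutral-mutation proxy (average
#' pairwise divergence of the two proxy samples at eligible sites).
#'
#' @param aln alignment over the whole region (reference sample first).
#' @param species factor/character of species labels, one per sequence.
#' @param cds CDS annotation data frame.
#' @param intervals data frame with `left`, `right` (bp, 1-based) and
#'   optionally `rate`.
#' @param focal species whose samples provide the polymorphism counts.
#' @param diverged species contrasted with `focal` for the divergence count.
#' @param proxy_pair two species whose divergence is the neutral-mutation
#'   proxy.
#' @param stream site stream passed to [eligible_mask()].
#' @param preference codon preference table.
#' @return Data frame, one row per interval: `left`, `right`, `eligible`,
#'   `polymorphic`, `divergence`, `div_eligible`, `gc`, `gene_density`,
#'   `mu`, plus `rate` when supplied.
#' @export
interval_summaries <- function(aln, species, cds, intervals,
                               focal, diverged, proxy_pair,
                               stream = "unpreferred",
                               preference = default_preference_table()) {
  m <- aln_matrix(aln)
  species <- as.character(species)
  stopifnot(length(species) == nrow(m))
  cls <- classify_sites(aln, cds, preference)
  foc <- m[species == focal, , drop = FALSE]
  dvg <- m[species == diverged, , drop = FALSE]
  prx <- m[species %in% proxy_pair, , drop = FALSE]
  elig_foc <- eligible_mask(foc, cls, stream)
  elig_pair <- eligible_mask(rbind(foc, dvg), cls, stream)
  elig_prx <- eligible_mask(prx, cls, stream)
  out <- lapply(seq_len(nrow(intervals)), function(k) {
    span <- intervals$left[k]:intervals$right[k]
    in_span <- logical(ncol(m)); in_span[span] <- TRUE
    pf <- polymorphic_fraction(foc, elig_foc & in_span)
    de <- sum(elig_pair & in_span)
    dv <- if (de > 0L) {
      d <- pairwise_divergence(foc, dvg, elig_pair & in_span)
      round(d$mean * de)
    } else 0L
    mu <- if (sum(elig_prx & in_span) > 0L && nrow(prx) >= 2L)
      pairwise_divergence(prx[1L, , drop = FALSE], prx[-1L, , drop = FALSE],
                          elig_prx & in_span)$mean else NA_real_
    data.frame(left = intervals$left[k], right = intervals$right[k],
               eligible = unname(pf["eligible"]),
               polymorphic = unname(pf["polymorphic"]),
               divergence = dv, div_eligible = de,
               gc = gc_content(paste(m[1L, span], collapse = "")),
               gene_density = gene_density_interval(cds, intervals$left[k],
                                                    intervals$right[k]),
               mu = mu)
  })
  out <- do.call(rbind, out)
  if (!is.null(intervals$rate)) out$rate <- intervals$rate
  out
}
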