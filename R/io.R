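#' Read and write the pipeline's tab-separated interchange files
#'
#' Genotype matrices travel as TSV with one row per individual and one
#' column per marker (codes 0 homozygous / 1 heterozygous, empty = missing);
#' marker maps as three-column TSV (`chrom`, `marker`, `pos`, 1-based);
#' interval maps as TSV with the full per-interval statistics and as BED
#' (0-based half-open, `name` = interval index, `score` = rate in cM/Mb).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @name recmapsel-io
NULL

#' @rdname recmapsel-io
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  write.table(as.data.frame(unclass(genotypes)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname recmapsel-io
#' @param markers a [marker_map()] to attach on read.
#' @export
read_genotypes_tsv <- function(path, markers) {
  d <- read.delim(path, check.names = FALSE)
  genotype_matrix(as.matrix(d), markers)
}

#' @rdname recmapsel-io
#' @export
write_marker_map_tsv <- function(markers, path) {
  write.table(as.data.frame(markers), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname recmapsel-io
#' @export
read_marker_map_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  marker_map(d$chrom, d$marker, d$pos)
}

#' @rdname recmapsel-io
#' @param map a `"recmap"` object or its `intervals` data frame.
#' @export
write_map_tsv <- function(map, path) {
  iv <- if (inherits(map, "recmap")) map$intervals else map
  write.table(iv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname recmapsel-io
#' @export
read_map_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname recmapsel-io
#' @export
write_map_bed <- function(map, path) {
  iv <- if (inherits(map, "recmap")) map$intervals else map
  bed <- data.frame(chrom = iv$chrom, start = iv$left - 1L, end = iv$right,
                    name = paste0("iv", seq_len(nrow(iv))),
                    score = iv$rate,
                    ci_low = iv$ci_low, ci_high = iv$ci_high)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CDS segments from a GFF3 file
#'
#' Imports the annotation with `rtracklayer` and returns the flat CDS table
#' ([classify_sites()]'s expected shape): `start`, `end` (1-based
#' inclusive), `strand`, `frame`, `gene` (from the `Parent` or `ID`
#' attribute).
#'
#' @param path GFF3 file.
#' @return CDS data frame.
#' @export
read_cds_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  gene <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0))
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1L))
  else as.character(gr$ID)
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             frame = as.integer(as.character(gr$phase)),
             gene = gene, stringsAsFactors = FALSE)
}

#' Read an alignment FASTA
#'
#' @param path FASTA of equal-length aligned sequences.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_alignment_fasta <- function(path) Biostrings::readDNAStringSet(path)
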