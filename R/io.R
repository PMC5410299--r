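#' Read and write feature coordinates as 6-column BED
#'
#' Coordinates are held in-package as a data.frame with columns `feature_id`,
#' `chrom`, `start` (0-based inclusive), `end` (0-based exclusive) and
#' `strand`, i.e. the BED convention. Serialization goes through
#' `rtracklayer`, which owns the 0-based/1-based bookkeeping.
#'
#' @param coords coordinate data.frame as above.
#' @param file path to a BED file.
#' @return `write_bed` returns `coords` invisibly; `read_bed` returns a
#'   coordinate data.frame.
#' @export
write_bed <- function(coords, file) {
  gr <- coords_to_granges(coords)
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, file, format = "BED")
  invisible(coords)
}

#' @rdname write_bed
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  granges_to_coords(gr)
}

#' Convert between coordinate data.frames and GRanges
#'
#' @param coords coordinate data.frame (see [write_bed()]).
#' @param gr a `GRanges` whose names are feature ids.
#' @return a `GRanges` / a coordinate data.frame.
#' @export
coords_to_granges <- function(coords) {
  validate_coords(coords)
  gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = coords$start + 1L, end = coords$end),
    strand = sub("\\.", "*", coords$strand))
  names(gr) <- coords$feature_id
  gr
}

#' @rdname coords_to_granges
#' @export
granges_to_coords <- function(gr) {
  nm <- names(gr)
  if (is.null(nm) && !is.null(S4Vectors::mcols(gr)$name))
    nm <- S4Vectors::mcols(gr)$name
  data.frame(
    feature_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE, row.names = NULL)
}

validate_coords <- function(coords) {
  need <- c("feature_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(coords)))
    input_error(paste("coordinate table needs columns:",
                      paste(need, collapse = ", ")))
  if (anyDuplicated(coords$feature_id))
    input_error("duplicate feature ids in coordinate table")
  if (any(coords$start < 0) || any(coords$start >= coords$end))
    input_error("coordinates must satisfy 0 <= start < end")
  invisible(coords)
}

#' Read and write annotation term sets as GMT
#'
#' Term sets are a named list of member-id character vectors. One line per
#' term: id, description, then members, tab-separated. Reading uses
#' `fgsea::gmtPathways` (descriptions are not retained).
#'
#' @param sets named list of character vectors.
#' @param file path to a GMT file.
#' @param descriptions optional character vector, recycled; defaults to the
#'   term ids.
#' @return `write_gmt` returns `sets` invisibly; `read_gmt` the named list.
#' @export
write_gmt <- function(sets, file, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(sets)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(file) {
  fgsea::gmtPathways(file)
}

#' Read and write promoter sequences as FASTA
#'
#' Promoters are a named character vector of upper-case DNA sequences.
#'
#' @param seqs named character vector over \{A,C,G,T,N\}.
#' @param file path to a FASTA file.
#' @return `write_fasta` returns `seqs` invisibly; `read_fasta` the named
#'   character vector.
#' @export
write_fasta <- function(seqs, file) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(seqs)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Read and write TF consensus motifs as a two-column table
#'
#' @param motifs data.frame with columns `tf_id`, `consensus` (IUPAC codes).
#' @param file path to a tab-separated file.
#' @return `write_motifs` returns `motifs` invisibly; `read_motifs` the
#'   data.frame.
#' @export
write_motifs <- function(motifs, file) {
  stopifnot(all(c("tf_id", "consensus") %in% names(motifs)))
  utils::write.table(motifs[, c("tf_id", "consensus")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(motifs)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read and write generic tab-separated tables
#'
#' Thin wrappers used for edge tables, DE tables, Ct tables and TF-target
#' tables so every artifact of the workflow round-trips through plain text.
#'
#' @param df a data.frame.
#' @param file path.
#' @return `write_tsv` returns `df` invisibly; `read_tsv` a data.frame.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
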