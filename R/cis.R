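#' Boundary gap between two genomic intervals
#'
#' Distance primitive for the cis-window rule. Intervals on different
#' chromosomes are incomparable (`NA`); overlapping or touching intervals
#' have gap 0; otherwise the gap between the closest ends. Coordinates
#' follow the package's BED convention (0-based half-open). Symmetric in its
#' arguments.
#'
#' @param a,b lists or one-row data.frames with fields `chrom`, `start`,
#'   `end`.
#' @return integer gap in bp, or `NA` if incomparable.
#' @export
interval_gap <- function(a, b) {
  if (a$start >= a$end || b$start >= b$end)
    input_error("intervals must satisfy start < end")
  if (!identical(as.character(a$chrom), as.character(b$chrom)))
    return(NA_integer_)
  as.integer(max(0, max(a$start, b$start) - min(a$end, b$end)))
}

#' Window neighbors: genes within a fixed distance of lncRNAs
#'
#' All same-chromosome (lncRNA, gene) pairs whose boundary gap is at most
#' `window` (boundary inclusive; the canonical window is 300 kbp up- or
#' downstream). Strand affects only the `relative_position` label
#' (upstream/downstream with respect to the lncRNA's strand; unstranded
#' lncRNAs are labeled as if on the plus strand), never inclusion.
#' Implemented over `GenomicRanges::findOverlaps` with `maxgap`.
#'
#' @param lnc_coords,gene_coords coordinate data.frames (see [write_bed()]).
#' @param window maximum boundary gap in bp.
#' @return data.frame `lnc_id`, `gene_id`, `chrom`, `distance`,
#'   `relative_position`, ordered by (chromosome, lncRNA start, gene start).
#' @export
window_neighbors <- function(lnc_coords, gene_coords, window = 300000) {
  validate_coords(lnc_coords)
  validate_coords(gene_coords)
  stopifnot(window >= 0)
  lnc_gr <- coords_to_granges(lnc_coords)
  gene_gr <- coords_to_granges(gene_coords)
  lv <- union(GenomeInfoDb::seqlevels(lnc_gr), GenomeInfoDb::seqlevels(gene_gr))
  GenomeInfoDb::seqlevels(lnc_gr) <- lv
  GenomeInfoDb::seqlevels(gene_gr) <- lv
  hits <- GenomicRanges::findOverlaps(lnc_gr, gene_gr, maxgap = window,
                                      ignore.strand = TRUE)
  li <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (!length(li))
    return(data.frame(lnc_id = character(0), gene_id = character(0),
                      chrom = character(0), distance = integer(0),
                      relative_position = character(0),
                      stringsAsFactors = FALSE))
  dist <- GenomicRanges::distance(lnc_gr[li], gene_gr[gi],
                                  ignore.strand = TRUE)
  ls <- lnc_coords$start[li]; le <- lnc_coords$end[li]
  gs <- gene_coords$start[gi]; ge <- gene_coords$end[gi]
  lstrand <- lnc_coords$strand[li]
  pos <- ifelse(dist == 0, "overlapping",
         ifelse(xor(ge <= ls, lstrand == "-"), "upstream", "downstream"))
  out <- data.frame(
    lnc_id = lnc_coords$feature_id[li],
    gene_id = gene_coords$feature_id[gi],
    chrom = lnc_coords$chrom[li],
    distance = as.integer(dist),
    relative_position = pos,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, ls, gs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate cis-regulatory pairs
#'
#' Intersects window neighbors with the passing coexpression edges: a gene
#' is a cis-regulatory candidate of a lncRNA when it lies within the window
#' *and* is a coexpression partner.
#'
#' @param candidates data.frame from [window_neighbors()].
#' @param coexpression_edges passing edge table (`lnc_id`, `mrna_id`).
#' @return list with `pairs` (the candidate rows that are also coexpressed,
#'   plus the edge `r`) and `counts` (data.frame `lnc_id`, `n_cis_genes`).
#' @export
cis_pairs <- function(candidates, coexpression_edges) {
  key_c <- paste(candidates$lnc_id, candidates$gene_id)
  key_e <- paste(coexpression_edges$lnc_id, coexpression_edges$mrna_id)
  keep <- key_c %in% key_e
  pairs <- candidates[keep, , drop = FALSE]
  if (nrow(pairs)) {
    m <- match(paste(pairs$lnc_id, pairs$gene_id), key_e)
    pairs$r <- if (!is.null(coexpression_edges$r))
      coexpression_edges$r[m] else NA_real_
  } else {
    pairs$r <- numeric(0)
  }
  rownames(pairs) <- NULL
  counts <- if (nrow(pairs)) {
    tab <- table(pairs$lnc_id)
    data.frame(lnc_id = names(tab), n_cis_genes = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(lnc_id = character(0), n_cis_genes = integer(0),
               stringsAsFactors = FALSE)
  }
  list(pairs = pairs, counts = counts)
}
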