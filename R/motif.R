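#' IUPAC consensus motif scanning
#'
#' Counts occurrences of a degenerate consensus motif in a promoter sequence,
#' on both strands (the reverse complement of the motif is scanned on the
#' forward sequence). Matching follows IUPAC degeneracy with one restriction:
#' an `N` in the subject sequence is only matched by an `N` in the motif —
#' unknown bases never satisfy a concrete code. Overlapping occurrences are
#' all counted. If the motif is its own reverse complement the two strands
#' would report identical occurrences, so they are counted once.
#'
#' This scanner is the package's replacement for external pairwise-alignment
#' tooling in the TF-binding step: an exact, auditable consensus matcher.
#'
#' @param promoter DNA string over \{A,C,G,T,N\} (case-insensitive).
#' @param motif IUPAC consensus string (or a list/data.frame row with a
#'   `consensus` field).
#' @return integer occurrence count (both strands).
#' @export
scan_motif <- function(promoter, motif) {
  if (is.list(motif)) motif <- motif$consensus
  stopifnot(is.character(promoter), length(promoter) == 1,
            is.character(motif), length(motif) == 1)
  promoter <- toupper(promoter)
  motif <- toupper(motif)
  if (!grepl("^[ACGTN]*$", promoter))
    input_error("promoter sequence may only contain A, C, G, T, N")
  if (!grepl(sprintf("^[%s]+$", paste(names(IUPAC_EXPANSION), collapse = "")),
             motif))
    input_error("motif may only contain IUPAC nucleotide codes")
  if (nchar(motif) > nchar(promoter)) return(0L)
  fwd <- count_consensus(promoter, motif)
  rc <- reverse_complement_iupac(motif)
  if (identical(rc, motif)) return(fwd)
  fwd + count_consensus(promoter, rc)
}

IUPAC_EXPANSION <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N")

# overlapping occurrence count of one consensus on the forward strand
count_consensus <- function(seq, motif) {
  classes <- IUPAC_EXPANSION[strsplit(motif, "")[[1]]]
  rx <- paste0("(?=", paste0("[", classes, "]", collapse = ""), ")")
  hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

reverse_complement_iupac <- function(motif) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(motif, "")[[1]]]), collapse = "")
}

#' Scan every TF motif against every lncRNA promoter
#'
#' @param promoters named character vector of promoter sequences (names are
#'   lncRNA ids).
#' @param motifs data.frame with columns `tf_id`, `consensus`.
#' @return data.frame `tf_id`, `lnc_id`, `n_sites` covering all pairs.
#' @export
scan_promoters <- function(promoters, motifs) {
  stopifnot(is.character(promoters), !is.null(names(promoters)))
  grid <- expand.grid(tf_id = motifs$tf_id, lnc_id = names(promoters),
                      stringsAsFactors = FALSE)
  cons <- stats::setNames(motifs$consensus, motifs$tf_id)
  grid$n_sites <- mapply(function(tf, lnc) scan_motif(promoters[[lnc]], cons[[tf]]),
                         grid$tf_id, grid$lnc_id, USE.NAMES = FALSE)
  grid[order(grid$tf_id, grid$lnc_id), , drop = FALSE]
}
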