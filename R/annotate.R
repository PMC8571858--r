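#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment under a match/mismatch/linear-gap
#' scoring triple, with deterministic tie-breaking in the traceback
#' (diagonal, then up, then left). Intended for transferring ITS annotation
#' between near-identical sequences, not for distant homology search.
#'
#' @param a,b Sequences: character strings, or lists with a `residues`
#'   element.
#' @param match,mismatch,gap Scoring parameters (defaults +1 / -1 / -2).
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @examples
#' global_align("ACGT", "AGT")$score  # 1: three matches, one gap
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  as_string <- function(x) {
    if (is.list(x) && !is.null(x$residues)) x <- x$residues
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
  a <- as_string(a); b <- as_string(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align empty sequences")
  out <- .nw_align(a, b, match, mismatch, gap)
  structure(out, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("global alignment, score", x$score, "\n")
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Transfer ITS annotation from a reference to a target sequence
#'
#' Aligns the annotated reference globally against the target and maps each
#' ITS1/5.8S/ITS2 interval boundary through the alignment into target
#' coordinates. Target insertions inside a region extend it; if the target
#' lacks a region entirely (the mapped interval is empty) an error names the
#' missing region.
#'
#' @param reference Reference sequence (string or list with `residues`).
#' @param reference_annotation An [its_annotation()] valid on the ungapped
#'   reference coordinates.
#' @param target Target sequence to annotate.
#' @param match,mismatch,gap Scoring passed to [global_align()].
#' @return An `its_annotation` in target coordinates.
#' @export
transfer_annotation <- function(reference, reference_annotation, target,
                                match = 1, mismatch = -1, gap = -2) {
  aln <- global_align(reference, target, match, mismatch, gap)
  ref <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
  tgt <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
  ref_pos <- cumsum(ref != "-")   # reference coordinate at each column
  tgt_cum <- cumsum(tgt != "-")   # target residues consumed through column
  n_ref <- max(ref_pos)
  map_interval <- function(iv, name) {
    if (iv[2L] > n_ref)
      stop("annotation interval '", name, "' exceeds reference length")
    col_s <- match(iv[1L], ref_pos)  # first column of the start residue
    col_e <- max(which(ref_pos == iv[2L]))  # last column covering the end
    s <- if (col_s == 1L) 1L else tgt_cum[col_s - 1L] + 1L
    e <- tgt_cum[col_e]
    if (e < s)
      stop("annotation transfer failed: target lacks region '", name, "'")
    c(s, e)
  }
  its_annotation(map_interval(reference_annotation$its1, "its1"),
                 map_interval(reference_annotation$r58s, "r58s"),
                 map_interval(reference_annotation$its2, "its2"))
}

#' Mask 5.8S columns of an alignment
#'
#' Sets the column mask to `FALSE` on every alignment column that intersects
#' the 5.8S interval of any member, where each member's interval (given in
#' its own ungapped coordinates) is projected through that member's gaps onto
#' alignment columns. The masked-out span of a member runs from the column of
#' its first 5.8S residue to the column of its last, so gap columns inside
#' the gene are masked too. ITS1/ITS2 columns keep their mask state.
#' Masking is idempotent and monotone: it only ever turns mask entries off.
#'
#' @param alignment A `labeled_alignment`.
#' @param annotations Named list, accession to [its_annotation()] (ungapped
#'   member coordinates). Alternatively a single annotation under the name
#'   `"columns"` interpreted directly in alignment-column coordinates. If
#'   `NULL`, the alignment is returned unchanged (documented default:
#'   all-true mask, 5.8S not excluded).
#' @return The alignment with an updated `mask`.
#' @export
mask_58s <- function(alignment, annotations) {
  if (is.null(annotations) || length(annotations) == 0L) return(alignment)
  drop <- rep(FALSE, ncol(alignment$seq))
  if (identical(names(annotations), "columns")) {
    iv <- annotations[["columns"]]$r58s
    drop[iv[1L]:min(iv[2L], length(drop))] <- TRUE
  } else {
    missing_ann <- setdiff(alignment$accession, names(annotations))
    if (length(missing_ann) > 0L)
      stop("missing annotation for member(s): ",
           paste(missing_ann, collapse = ", "))
    for (acc in alignment$accession) {
      iv <- annotations[[acc]]$r58s
      row <- alignment$seq[acc, ]
      pos <- cumsum(row != "-")
      cols <- which(row != "-" & pos >= iv[1L] & pos <= iv[2L])
      if (length(cols) > 0L) drop[min(cols):max(cols)] <- TRUE
    }
  }
  alignment$mask <- alignment$mask & !drop
  alignment
}
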