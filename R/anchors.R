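#' Read an anchor table
#'
#' An anchor table ties generic alignment positions to native (author)
#' residue numbers per taxon, organised in per-helix contiguity blocks:
#' within a block, native number differences equal alignment position
#' differences, so a single anchored cell determines the whole block.
#'
#' @param path TSV with columns taxon, block, block_aln_start, block_aln_end,
#'   aln_pos, native, aa; lines starting with \code{#} are comments. Default:
#'   the packaged residue-mapping table for the nuclear receptors with
#'   published LBD structures.
#' @return data.frame of class \code{anchor_table}.
#' @export
read_anchor_table <- function(path = system.file("extdata", "table1_anchors.tsv",
                                                 package = "nrpiturn")) {
  at <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("taxon", "block", "block_aln_start", "block_aln_end",
            "aln_pos", "native", "aa")
  if (!all(need %in% names(at))) stop("anchor table lacks required columns")
  # audit the contiguity invariant
  for (k in unique(paste(at$taxon, at$block))) {
    sub <- at[paste(at$taxon, at$block) == k, , drop = FALSE]
    if (nrow(sub) > 1) {
      d <- diff(sub$native) - diff(sub$aln_pos)
      if (any(d != 0)) stop("contiguity violated in block ", k)
    }
    if (any(sub$aln_pos < sub$block_aln_start | sub$aln_pos > sub$block_aln_end))
      stop("anchor outside its block range in ", k)
  }
  class(at) <- c("anchor_table", "data.frame")
  at
}

#' Map a generic alignment position to a native residue number
#'
#' \code{native = anchor native + (position - anchor alignment position)}
#' within the contiguity block containing \code{position}.
#'
#' @param anchors an \code{\link{read_anchor_table}} result.
#' @param taxon taxon label as used in the table.
#' @param position generic alignment position (1-based).
#' @return list with \code{native} (residue number) and \code{aa} (expected
#'   amino acid at that position when the table anchors it, else NA).
#' @export
map_alignment_to_native <- function(anchors, taxon, position) {
  sub <- anchors[anchors$taxon == taxon, , drop = FALSE]
  if (!nrow(sub)) stop("taxon not in anchor table: ", taxon)
  inblk <- sub[sub$block_aln_start <= position & sub$block_aln_end >= position, , drop = FALSE]
  if (!nrow(inblk))
    stop("unanchored position ", position, " for taxon ", taxon)
  a <- inblk[1, ]
  native <- a$native + (position - a$aln_pos)
  exact <- inblk[inblk$aln_pos == position, , drop = FALSE]
  list(native = native, aa = if (nrow(exact)) exact$aa[1] else NA_character_)
}

#' Map a native residue number back to its generic alignment position
#'
#' Exact inverse of \code{\link{map_alignment_to_native}} on anchored spans.
#'
#' @inheritParams map_alignment_to_native
#' @param native native (author) residue number.
#' @return generic alignment position (integer).
#' @export
map_native_to_alignment <- function(anchors, taxon, native) {
  sub <- anchors[anchors$taxon == taxon, , drop = FALSE]
  if (!nrow(sub)) stop("taxon not in anchor table: ", taxon)
  for (b in unique(sub$block)) {
    blk <- sub[sub$block == b, , drop = FALSE]
    a <- blk[1, ]
    pos <- a$aln_pos + (native - a$native)
    if (pos >= a$block_aln_start && pos <= a$block_aln_end) return(as.integer(pos))
  }
  stop("unanchored position: native ", native, " for taxon ", taxon)
}
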