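#' Default distance cutoffs for interface contact typing
#' @return named list: hbond 3.5, salt_bridge 4.0, vdw 4.5, water 3.5 (all
#'   Angstroms). The structures this is applied to lack hydrogens, so the
#'   hydrogen-bond criterion is heavy-atom distance only.
#' @export
default_contact_cutoffs <- function() {
  list(hbond = 3.5, salt_bridge = 4.0, vdw = 4.5, water = 3.5)
}

#' Enumerate and type inter-subunit contacts
#'
#' Contact types, in order of precedence on a shared atom pair:
#' \itemize{
#'   \item \code{salt_bridge}: basic/acidic side-chain pair within
#'     \code{cutoffs$salt_bridge} (see \code{\link{detect_salt_bridges}});
#'   \item \code{hbond}: polar heavy-atom pair (N/O to N/O) within
#'     \code{cutoffs$hbond};
#'   \item \code{vdw}: any remaining heavy-atom pair within
#'     \code{cutoffs$vdw}.
#' }
#' Additionally, a water whose O lies within \code{cutoffs$water} of a polar
#' atom of each chain yields one \code{water_mediated} record per bridged
#' residue pair (exactly one bridging water; water chains are not followed).
#' Records are deduplicated to one per (residue pair, type) keeping the
#' minimal distance.
#'
#' @param s an \code{\link{nr_structure}}.
#' @param chainA,chainB chain identifiers; both must exist.
#' @param cutoffs see \code{\link{default_contact_cutoffs}}.
#' @return data.frame: chainA, resnoA, residA, atomA, chainB, resnoB, residB,
#'   atomB, type, distance, water (water residue number for water_mediated,
#'   else NA).
#' @export
enumerate_interface_contacts <- function(s, chainA, chainB,
                                         cutoffs = default_contact_cutoffs()) {
  stopifnot(inherits(s, "nr_structure"))
  for (ch in c(chainA, chainB))
    if (!any(s$chain == ch & s$resid != "HOH")) stop("chain absent: ", ch)
  A <- as.data.frame(s[s$chain == chainA & s$resid != "HOH" & s$elesy != "H", ])
  B <- as.data.frame(s[s$chain == chainB & s$resid != "HOH" & s$elesy != "H", ])
  am <- as.matrix(A[, c("x", "y", "z")]); bm <- as.matrix(B[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm))
  idx <- which(d <= max(cutoffs$vdw, cutoffs$hbond, cutoffs$salt_bridge), arr.ind = TRUE)
  rec <- NULL
  if (nrow(idx)) {
    rec <- data.frame(
      chainA = chainA, resnoA = A$resno[idx[, 1]], residA = A$resid[idx[, 1]],
      atomA = A$elety[idx[, 1]],
      chainB = chainB, resnoB = B$resno[idx[, 2]], residB = B$resid[idx[, 2]],
      atomB = B$elety[idx[, 2]], distance = d[idx], stringsAsFactors = FALSE)
    is_basic <- function(resid, atom) {
      out <- rep(FALSE, length(resid))
      for (rn in names(SB_BASIC)) out <- out | (resid == rn & atom %in% SB_BASIC[[rn]])
      out
    }
    is_acidic <- function(resid, atom) {
      out <- rep(FALSE, length(resid))
      for (rn in names(SB_ACIDIC)) out <- out | (resid == rn & atom %in% SB_ACIDIC[[rn]])
      out
    }
    polarA <- A$elesy[idx[, 1]] %in% c("N", "O")
    polarB <- B$elesy[idx[, 2]] %in% c("N", "O")
    sb <- ((is_basic(rec$residA, rec$atomA) & is_acidic(rec$residB, rec$atomB)) |
           (is_acidic(rec$residA, rec$atomA) & is_basic(rec$residB, rec$atomB))) &
          rec$distance <= cutoffs$salt_bridge
    hb <- polarA & polarB & rec$distance <= cutoffs$hbond & !sb
    vdw <- !sb & !hb & rec$distance <= cutoffs$vdw
    rec$type <- ifelse(sb, "salt_bridge", ifelse(hb, "hbond", ifelse(vdw, "vdw", NA)))
    rec <- rec[!is.na(rec$type), , drop = FALSE]
    rec$water <- NA_integer_
  }
  # water-mediated: one bridging water O within cutoff of a polar atom of each chain
  wat <- as.data.frame(s[s$resid == "HOH" & s$elety == "O", ])
  wrec <- NULL
  if (nrow(wat)) {
    polA <- A[A$elesy %in% c("N", "O"), , drop = FALSE]
    polB <- B[B$elesy %in% c("N", "O"), , drop = FALSE]
    if (nrow(polA) && nrow(polB)) {
      wm <- as.matrix(wat[, c("x", "y", "z")])
      dA <- sqrt(outer(rowSums(wm^2), rowSums(as.matrix(polA[, c("x","y","z")])^2), `+`) -
                 2 * wm %*% t(as.matrix(polA[, c("x","y","z")])))
      dB <- sqrt(outer(rowSums(wm^2), rowSums(as.matrix(polB[, c("x","y","z")])^2), `+`) -
                 2 * wm %*% t(as.matrix(polB[, c("x","y","z")])))
      rows <- list()
      for (w in seq_len(nrow(wat))) {
        ia <- which(dA[w, ] <= cutoffs$water)
        ib <- which(dB[w, ] <= cutoffs$water)
        if (!length(ia) || !length(ib)) next
        for (i in ia) for (j in ib) {
          rows[[length(rows) + 1L]] <- data.frame(
            chainA = chainA, resnoA = polA$resno[i], residA = polA$resid[i],
            atomA = polA$elety[i],
            chainB = chainB, resnoB = polB$resno[j], residB = polB$resid[j],
            atomB = polB$elety[j], distance = dA[w, i] + dB[w, j],
            type = "water_mediated", water = wat$resno[w],
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) wrec <- do.call(rbind, rows)
    }
  }
  rec <- rbind(rec, wrec)
  empty <- data.frame(chainA = character(), resnoA = integer(), residA = character(),
                      atomA = character(), chainB = character(), resnoB = integer(),
                      residB = character(), atomB = character(), distance = numeric(),
                      type = character(), water = integer())
  if (is.null(rec) || !nrow(rec)) return(empty)
  key <- paste(rec$resnoA, rec$resnoB, rec$type)
  rec <- rec[order(key, rec$distance), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$resnoA, rec$resnoB, rec$type)), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Define named secondary-structure elements per chain
#'
#' @param ranges named list: chain -> named list of elements
#'   (\code{H7}, \code{H8}, \code{loopH8-H9}, \code{H9}, \code{H10},
#'   \code{H11}, ...) -> c(first resno, last resno). Ranges must not overlap
#'   within a chain; unlisted residues bin as \code{"other"}.
#' @return object of class \code{element_map}.
#' @export
element_map <- function(ranges) {
  for (ch in names(ranges)) {
    el <- ranges[[ch]]
    iv <- do.call(rbind, el)
    if (!is.null(iv) && nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping element ranges in chain ", ch)
    }
  }
  structure(ranges, class = "element_map")
}

element_of <- function(em, chain, resno) {
  el <- em[[chain]]
  if (is.null(el)) return(rep("other", length(resno)))
  out <- rep("other", length(resno))
  for (nm in names(el))
    out[resno >= el[[nm]][1] & resno <= el[[nm]][2]] <- nm
  out
}

#' Bin interface contacts by secondary-structure element pairs
#'
#' @param contacts output of \code{\link{enumerate_interface_contacts}}.
#' @param em an \code{\link{element_map}}.
#' @param anchors optional \code{\link{read_anchor_table}}; when supplied
#'   together with \code{taxonA}, contacts whose A-side residue maps to the
#'   pi-turn motif positions (alignment 202, 205, 206, 210) are tallied in
#'   \code{pi_turn_contacts}.
#' @param taxonA taxon label of chain A in the anchor table.
#' @return object of class \code{element_contact_matrix}: data.frame
#'   \code{counts} (elementA, elementB, type, n), total, and the pi-turn
#'   subset count.
#' @export
bin_contacts_by_element <- function(contacts, em, anchors = NULL, taxonA = NULL) {
  if (nrow(contacts)) {
    ea <- element_of(em, contacts$chainA[1], contacts$resnoA)
    eb <- element_of(em, contacts$chainB[1], contacts$resnoB)
    counts <- stats::aggregate(list(n = rep(1L, nrow(contacts))),
                               by = list(elementA = ea, elementB = eb,
                                         type = contacts$type), FUN = sum)
  } else {
    counts <- data.frame(elementA = character(), elementB = character(),
                         type = character(), n = integer())
  }
  pi_n <- NA_integer_
  if (!is.null(anchors) && !is.null(taxonA) && nrow(contacts)) {
    pi_nat <- vapply(c(202L, 205L, 206L, 210L), function(p)
      tryCatch(map_alignment_to_native(anchors, taxonA, p)$native,
               error = function(e) NA_integer_), integer(1))
    pi_n <- sum(contacts$resnoA %in% pi_nat)
  }
  structure(list(counts = counts, total = sum(counts$n),
                 pi_turn_contacts = pi_n),
            class = "element_contact_matrix")
}

#' Signed interface asymmetry score
#'
#' \code{count(H7_A, loopH8-H9_B) - count(H7_B, loopH8-H9_A)}: positive when
#' chain A behaves like RXR in a heterodimer (its helix H7, bearing the
#' pi-turn, packs against the partner's loop H8-H9 more than the reverse);
#' 0 for a symmetric interface. The reverse-orientation count is taken from
#' a second contact matrix computed with the chains swapped.
#'
#' @param m element contact matrix for orientation (A, B).
#' @param m_rev element contact matrix for orientation (B, A).
#' @return signed integer score.
#' @export
asymmetry_score <- function(m, m_rev) {
  pick <- function(mm) {
    cc <- mm$counts
    sum(cc$n[cc$elementA == "H7" & cc$elementB == "loopH8-H9"])
  }
  pick(m) - pick(m_rev)
}
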