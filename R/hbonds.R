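#' Place backbone amide hydrogens
#'
#' Crystal structures lack hydrogens; the Kabsch-Sander energy needs the
#' amide H. It is placed at N + 1.0 Angstrom along the unit vector
#' (C_prev - O_prev), i.e. anti-parallel to the preceding carbonyl. Prolines
#' and chain-start residues receive no H; residues whose predecessor lacks
#' C or O are skipped.
#'
#' @param s an \code{\link{nr_structure}}.
#' @return the structure with \code{"H"} atoms appended per residue.
#' @export
place_backbone_hydrogens <- function(s) {
  stopifnot(inherits(s, "nr_structure"))
  new_rows <- list()
  for (ch in unique(s$chain[s$resid != "HOH"])) {
    res <- residue_table(s, ch)
    if (nrow(res) < 2) next
    N <- atom_coords(s, ch, "N")
    C <- atom_coords(s, ch, "C")
    O <- atom_coords(s, ch, "O")
    for (i in 2:nrow(res)) {
      if (res$resid[i] == "PRO") next
      if (anyNA(N[i, ]) || anyNA(C[i - 1, ]) || anyNA(O[i - 1, ])) next
      h <- N[i, ] + unit(C[i - 1, ] - O[i - 1, ]) * 1.0
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        chain = ch, resno = res$resno[i], ins = res$ins[i], resid = res$resid[i],
        elety = "H", elesy = "H", x = h[1], y = h[2], z = h[3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(new_rows)) return(s)
  out <- rbind(as.data.frame(s), do.call(rbind, new_rows))
  # keep residue blocks together, in original residue order per chain
  out <- out[order(match(out$chain, unique(s$chain)), out$resno, out$ins), ]
  rownames(out) <- NULL
  nr_structure(out)
}

#' Backbone hydrogen bonds by the Kabsch-Sander electrostatic model
#'
#' For each donor residue i (with N and H) and acceptor residue j (with C and
#' O) in the same chain with sequence separation |i - j| >= 2, the energy is
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol. A bond is
#' recorded when E < \code{energy_cutoff}; at most the two best (lowest
#' energy) acceptors per donor are retained.
#'
#' @param s structure with hydrogens placed
#'   (\code{\link{place_backbone_hydrogens}}).
#' @param energy_cutoff kcal/mol, default -0.5.
#' @return data.frame with columns \code{chain}, \code{donor} and
#'   \code{acceptor} (residue indices within the chain, 1-based),
#'   \code{donor_resno}, \code{acceptor_resno} (author numbers),
#'   \code{energy} (kcal/mol) and \code{offset} (donor index minus acceptor
#'   index).
#' @export
compute_hbonds_ks <- function(s, energy_cutoff = -0.5) {
  stopifnot(inherits(s, "nr_structure"))
  out <- list()
  for (ch in unique(s$chain[s$resid != "HOH"])) {
    res <- residue_table(s, ch)
    n <- nrow(res)
    if (n < 3) next
    N <- atom_coords(s, ch, "N")
    H <- atom_coords(s, ch, "H")
    C <- atom_coords(s, ch, "C")
    O <- atom_coords(s, ch, "O")
    donors <- which(stats::complete.cases(N) & stats::complete.cases(H))
    acceptors <- which(stats::complete.cases(C) & stats::complete.cases(O))
    if (!length(donors) || !length(acceptors)) next
    d2 <- function(A, B) sqrt(rowSums((A - B)^2))
    for (i in donors) {
      j <- acceptors[abs(acceptors - i) >= 2]
      if (!length(j)) next
      rON <- d2(O[j, , drop = FALSE], matrix(N[i, ], length(j), 3, byrow = TRUE))
      rCH <- d2(C[j, , drop = FALSE], matrix(H[i, ], length(j), 3, byrow = TRUE))
      rOH <- d2(O[j, , drop = FALSE], matrix(H[i, ], length(j), 3, byrow = TRUE))
      rCN <- d2(C[j, , drop = FALSE], matrix(N[i, ], length(j), 3, byrow = TRUE))
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      keep <- which(E < energy_cutoff)
      if (!length(keep)) next
      keep <- keep[order(E[keep])][seq_len(min(2L, length(keep)))]
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, donor = i, acceptor = j[keep],
        donor_resno = res$resno[i], acceptor_resno = res$resno[j[keep]],
        energy = E[keep], offset = i - j[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), donor = integer(), acceptor = integer(),
                      donor_resno = integer(), acceptor_resno = integer(),
                      energy = numeric(), offset = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
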