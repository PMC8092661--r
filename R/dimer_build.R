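#' Build a two-chain toy dimer with designed salt bridges
#'
#' Two copies of an ideal alpha helix are placed as chains A and B separated
#' by \code{separation} Angstroms perpendicular to the helix axis. Each
#' requested bridge pair receives one pseudo side-chain atom per residue
#' (Arg-like nitrogen \code{NH1} on chain A, Glu-like oxygen \code{OE1} on
#' chain B) placed on the inter-CA segment so that the pair sits at exactly
#' the target distance. A residue may appear in at most one bridge pair.
#' After construction the builder verifies that all non-designed inter-chain
#' atom pairs are farther apart than the van der Waals cutoff + 1 Angstrom
#' and that the designed distances were realised; contradictory geometry is
#' an error.
#'
#' @param n_res_per_chain residues per helix.
#' @param separation inter-chain offset in Angstroms (> 0).
#' @param bridge_pairs data.frame with columns \code{resA}, \code{resB},
#'   \code{dist} (target distances >= 2.5), or NULL for none.
#' @param vdw_cutoff the downstream van der Waals contact cutoff the
#'   clearance check protects (default 4.5).
#' @return an \code{\link{nr_structure}} with chains A and B.
#' @export
make_toy_dimer <- function(n_res_per_chain, separation, bridge_pairs = NULL,
                           vdw_cutoff = 4.5) {
  if (separation <= 0) stop("separation must be > 0")
  if (!is.null(bridge_pairs)) {
    stopifnot(all(c("resA", "resB", "dist") %in% names(bridge_pairs)))
    if (any(bridge_pairs$dist < 2.5)) stop("target distances must be >= 2.5 Angstroms")
    if (anyDuplicated(bridge_pairs$resA) || anyDuplicated(bridge_pairs$resB))
      stop("contradictory geometry: a residue appears in more than one bridge pair")
    if (any(bridge_pairs$resA > n_res_per_chain | bridge_pairs$resB > n_res_per_chain |
            bridge_pairs$resA < 1 | bridge_pairs$resB < 1))
      stop("bridge residue outside 1..n_res_per_chain")
  }
  a <- make_ideal_helix(helix_spec("alpha", n_res_per_chain, chain_id = "A"))
  b <- as.data.frame(a)
  b$chain <- "B"
  # displace chain B perpendicular to the helix axis (first principal axis of CA)
  CA <- atom_coords(a, "A", "CA")
  sv <- svd(sweep(CA, 2, colMeans(CA)))
  axis <- sv$v[, 1]
  perp <- unit(sv$v[, 2])
  b[, c("x", "y", "z")] <- sweep(as.matrix(b[, c("x", "y", "z")]), 2,
                                 perp * separation, `+`)
  atoms <- rbind(as.data.frame(a), b)
  if (!is.null(bridge_pairs) && nrow(bridge_pairs)) {
    CAb <- sweep(CA, 2, perp * separation, `+`)
    extra <- list()
    for (i in seq_len(nrow(bridge_pairs))) {
      ra <- bridge_pairs$resA[i]; rb <- bridge_pairs$resB[i]; d <- bridge_pairs$dist[i]
      pA <- CA[ra, ]; pB <- CAb[rb, ]
      gap <- vec_norm(pB - pA)
      if (gap < d) stop("contradictory geometry: CA-CA gap (", round(gap, 2),
                        ") shorter than target distance ", d)
      u <- unit(pB - pA)
      m <- (pA + pB) / 2
      qA <- m - u * d / 2
      qB <- m + u * d / 2
      extra[[length(extra) + 1L]] <- data.frame(
        chain = c("A", "B"), resno = c(ra, rb), ins = "",
        resid = c("ARG", "GLU"), elety = c("NH1", "OE1"), elesy = c("N", "O"),
        x = c(qA[1], qB[1]), y = c(qA[2], qB[2]), z = c(qA[3], qB[3]),
        stringsAsFactors = FALSE)
      atoms$resid[atoms$chain == "A" & atoms$resno == ra] <- "ARG"
      atoms$resid[atoms$chain == "B" & atoms$resno == rb] <- "GLU"
    }
    atoms <- rbind(atoms, do.call(rbind, extra))
    atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$resno), ]
    rownames(atoms) <- NULL
  }
  s <- nr_structure(atoms)
  # clearance audit: every inter-chain pair not part of a designed bridge
  # must clear the VdW cutoff + 1 A
  A <- as.data.frame(s[s$chain == "A", ]); B <- as.data.frame(s[s$chain == "B", ])
  am <- as.matrix(A[, c("x", "y", "z")]); bm <- as.matrix(B[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(am^2), rowSums(bm^2), `+`) - 2 * am %*% t(bm))
  designed <- matrix(FALSE, nrow(A), nrow(B))
  if (!is.null(bridge_pairs) && nrow(bridge_pairs)) {
    for (i in seq_len(nrow(bridge_pairs))) {
      ia <- which(A$resno == bridge_pairs$resA[i] & A$elety == "NH1")
      ib <- which(B$resno == bridge_pairs$resB[i] & B$elety == "OE1")
      designed[ia, ib] <- TRUE
      if (abs(d[ia, ib] - bridge_pairs$dist[i]) > 1e-6)
        stop("internal error: designed distance not realised")
    }
  }
  if (any(d[!designed] <= vdw_cutoff + 1))
    stop("contradictory geometry: separation ", separation,
         " leaves non-designed inter-chain atoms within the clearance margin")
  s
}
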