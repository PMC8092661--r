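VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); same point set for every atom, so areas are exactly reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Each atom's sphere of radius r + probe is sampled with a fixed
#' deterministic point set; a point is accessible when it lies outside every
#' neighbour's solvent-expanded sphere. Waters are excluded from the
#' calculation. Unknown elements fall back to the carbon radius.
#'
#' @param s an \code{\link{nr_structure}}.
#' @param probe probe radius in Angstroms (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @return numeric vector of per-atom areas in square Angstroms, aligned
#'   with the non-water rows of \code{s} (names chain.resno.atom).
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "nr_structure"))
  a <- as.data.frame(s[s$resid != "HOH", , drop = FALSE])
  r <- VDW_RADII[a$elesy]
  unknown <- is.na(r)
  if (any(unknown)) {
    message("unknown element(s) ", paste(unique(a$elesy[unknown]), collapse = ", "),
            ": using carbon radius")
    r[unknown] <- VDW_RADII[["C"]]
  }
  r <- unname(r) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbour lists once, O(n^2) distances; structures here are desk-scale
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dd <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
            (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dd >= r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  names(areas) <- paste(a$chain, a$resno, a$elety, sep = ".")
  areas
}

#' Buried surface area of a two-chain interface
#'
#' BSA = SASA(A alone) + SASA(B alone) - SASA(complex), over the two named
#' chains only (other chains and waters are ignored). Symmetric in chain
#' order by construction.
#'
#' @param s an \code{\link{nr_structure}}.
#' @param chainA,chainB chain identifiers.
#' @inheritParams compute_sasa
#' @return buried area in square Angstroms.
#' @export
buried_surface_area <- function(s, chainA, chainB, probe = 1.4, n_points = 960L) {
  for (ch in c(chainA, chainB))
    if (!any(s$chain == ch & s$resid != "HOH")) stop("chain absent: ", ch)
  sub <- function(ch) nr_structure(as.data.frame(s[s$chain %in% ch & s$resid != "HOH", ]))
  sa <- sum(compute_sasa(sub(chainA), probe, n_points))
  sb <- sum(compute_sasa(sub(chainB), probe, n_points))
  sab <- sum(compute_sasa(sub(c(chainA, chainB)), probe, n_points))
  sa + sb - sab
}
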