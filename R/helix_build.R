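#' Default backbone dihedrals for the three helix classes
#'
#' Standard tabulated values: alpha (-57, -47), 3-10 (-49, -26),
#' pi (-57, -70) degrees.
#' @return named list mapping class to c(phi, psi) in degrees.
#' @export
default_phi_psi <- function() {
  list(alpha = c(-57, -47), three_ten = c(-49, -26), pi = c(-57, -70))
}

#' Specify a composite helix
#'
#' @param classes character vector of segment classes, each one of
#'   \code{"alpha"}, \code{"three_ten"}, \code{"pi"} (or \code{"coil"} for an
#'   extended stretch in test fixtures).
#' @param lengths integer vector of per-segment residue counts (all >= 1).
#' @param residue_name 3-letter residue code used for every residue.
#' @param chain_id single chain identifier.
#' @return object of class \code{helix_spec}.
#' @export
helix_spec <- function(classes, lengths, residue_name = "ALA", chain_id = "A") {
  allowed <- c("alpha", "three_ten", "pi", "coil")
  if (length(classes) != length(lengths)) stop("classes and lengths differ in length")
  if (!all(classes %in% allowed))
    stop("unknown helix_class: ", paste(setdiff(classes, allowed), collapse = ", "))
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("every segment length must be >= 1")
  if (sum(lengths) < 6L) stop("total length must be >= 6 (minimum for one N+5 bond)")
  structure(list(classes = classes, lengths = lengths,
                 residue_name = residue_name, chain_id = chain_id),
            class = "helix_spec")
}

#' Build an ideal poly-residue backbone from a helix specification
#'
#' Chain extension with standard internal coordinates (N-CA 1.458, CA-C 1.525,
#' C-N 1.329 Angstroms; omega fixed at 180 degrees), per-segment (phi, psi)
#' taken from \code{phi_psi}. Atoms N, CA, C, O per residue; residues numbered
#' 1..n without gaps. Side chains are not built: downstream H-bond analysis
#' consumes only the backbone.
#'
#' @param spec a \code{\link{helix_spec}}.
#' @param phi_psi named list mapping class to c(phi, psi) degrees; entries in
#'   (-180, 180].
#' @return an \code{\link{nr_structure}}.
#' @export
make_ideal_helix <- function(spec, phi_psi = default_phi_psi()) {
  stopifnot(inherits(spec, "helix_spec"))
  if (!"coil" %in% names(phi_psi)) phi_psi$coil <- c(-120, 120)
  for (cl in unique(spec$classes)) {
    pp <- phi_psi[[cl]]
    if (is.null(pp) || length(pp) != 2) stop("phi_psi lacks an entry for class ", cl)
    if (any(pp <= -180 | pp > 180)) stop("phi/psi must lie in (-180, 180]")
  }
  n <- sum(spec$lengths)
  phi <- rep(vapply(spec$classes, function(cl) phi_psi[[cl]][1], 0), spec$lengths)
  psi <- rep(vapply(spec$classes, function(cl) phi_psi[[cl]][2], 0), spec$lengths)

  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  omega <- 180

  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  # seed the first residue in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  th <- deg2rad(a_NCAC)
  C[1, ] <- CA[1, ] + b_CAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_CN, a_CACN, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_NCA, a_CNCA, omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], b_CAC, a_NCAC, phi[i])
    }
  }
  # carbonyl oxygens need the next residue's N, hence a second pass
  for (i in seq_len(n)) {
    if (i < n) {
      # O anti to the next amide N across the C(i) plane
      O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], b_CO, a_CACO, 180)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_CO, a_CACO, psi[i] + 180)
    }
  }
  atoms <- data.frame(
    chain = spec$chain_id,
    resno = rep(seq_len(n), each = 4L),
    ins = "",
    resid = spec$residue_name,
    elety = rep(c("N", "CA", "C", "O"), n),
    elesy = rep(c("N", "C", "C", "O"), n),
    x = as.vector(rbind(N[, 1], CA[, 1], C[, 1], O[, 1])),
    y = as.vector(rbind(N[, 2], CA[, 2], C[, 2], O[, 2])),
    z = as.vector(rbind(N[, 3], CA[, 3], C[, 3], O[, 3])),
    stringsAsFactors = FALSE)
  s <- nr_structure(atoms)
  attr(s, "planted") <- data.frame(
    class = spec$classes,
    start = cumsum(c(1L, spec$lengths))[seq_along(spec$lengths)],
    end = cumsum(spec$lengths))
  s
}
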