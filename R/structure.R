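#' Atomic structure container
#'
#' A structure is stored as a flat atom table, one row per atom, with
#' columns \code{chain}, \code{resno} (author numbering, preserved verbatim),
#' \code{ins} (insertion code, \code{""} when none), \code{resid} (3-letter
#' residue name), \code{elety} (atom name, e.g. \code{"CA"}), \code{elesy}
#' (element symbol) and Cartesian \code{x}, \code{y}, \code{z} in Angstroms.
#' Waters are ordinary rows with \code{resid == "HOH"}.
#'
#' @param atoms data.frame with the columns above.
#' @return object of class \code{nr_structure} (a data.frame).
#' @export
nr_structure <- function(atoms) {
  need <- c("chain", "resno", "ins", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  atoms$resno <- as.integer(atoms$resno)
  # residues strictly ordered by (resno, ins) within each chain
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch & atoms$resid != "HOH", , drop = FALSE]
    key <- unique(paste(sub$resno, sub$ins, sep = "_"))
    ord <- unique(sub[order(sub$resno, sub$ins), c("resno", "ins")])
    keyo <- paste(ord$resno, ord$ins, sep = "_")
    if (!identical(key, keyo))
      stop("residues of chain ", ch, " are not in increasing (resno, ins) order")
  }
  class(atoms) <- c("nr_structure", "data.frame")
  atoms
}

#' @export
print.nr_structure <- function(x, ...) {
  prot <- x[x$resid != "HOH", , drop = FALSE]
  nres <- nrow(unique(prot[, c("chain", "resno", "ins")]))
  cat("<nr_structure> ", nrow(x), " atoms, ", nres, " residues, chains: ",
      paste(sort(unique(x$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' Parses the first model only. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically by altloc), unless
#' \code{keep_altloc} asks for a specific conformer. Waters are retained.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"cif"} or \code{"auto"} (by extension).
#' @param keep_altloc \code{NULL} (resolve by occupancy) or a single altloc
#'   character to extract that conformer.
#' @return an \code{\link{nr_structure}}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), keep_altloc = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  at <- tryCatch({
    if (format == "pdb") {
      pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
      pdb$atom
    } else {
      cif <- read_cif_atoms(path)
      names(cif)[names(cif) == "ins"] <- "insert"
      names(cif)[names(cif) == "occ"] <- "o"
      cif
    }
  }, error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                              conditionMessage(e)))
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  alt <- at$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(at))
  alt[is.na(alt) | alt == ""] <- ""
  occ <- at$o
  if (is.null(occ)) occ <- rep(1, nrow(at))
  occ[is.na(occ)] <- 1
  if (!is.null(keep_altloc)) {
    keep <- alt == "" | alt == keep_altloc
    at <- at[keep, , drop = FALSE]
  } else if (any(alt != "")) {
    # per (chain, residue, atom): best occupancy, then alphabetical altloc
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), , drop = FALSE]
    at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert), , drop = FALSE]
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  bad <- is.na(elesy) | elesy == ""
  elesy[bad] <- substr(gsub("[^A-Za-z].*$", "", at$elety[bad]), 1, 1)
  nr_structure(data.frame(
    chain = at$chain, resno = at$resno, ins = ins,
    resid = at$resid, elety = at$elety, elesy = toupper(elesy),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write a structure as a minimal single-model PDB file
#'
#' ATOM records only, author numbering preserved, no connectivity.
#'
#' @param s an \code{\link{nr_structure}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "nr_structure"))
  fmt_name <- function(elety, elesy) {
    # PDB atom-name column convention: element right-justified in cols 13-14
    ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
           ifelse(nchar(elesy) == 1, sprintf(" %-3s", elety), sprintf("%-4s", elety)))
  }
  lines <- sprintf("ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(s)), fmt_name(s$elety, s$elesy), " ",
                   s$resid, s$chain, s$resno, ifelse(s$ins == "", " ", s$ins),
                   s$x, s$y, s$z, 1.00, 0.00, s$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Residue-level view: list of data.frames in chain order, plus an index table.
residue_table <- function(s, chain = NULL, include_water = FALSE) {
  a <- s
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!include_water) a <- a[a$resid != "HOH", , drop = FALSE]
  if (nrow(a) == 0L) return(data.frame(chain = character(), resno = integer(),
                                       ins = character(), resid = character()))
  unique(a[, c("chain", "resno", "ins", "resid")])
}

# xyz of one named atom for every residue of `chain`, NA rows where absent.
atom_coords <- function(s, chain, elety) {
  res <- residue_table(s, chain)
  m <- matrix(NA_real_, nrow(res), 3)
  sub <- s[s$chain == chain & s$elety == elety & s$resid != "HOH", , drop = FALSE]
  idx <- match(paste(sub$resno, sub$ins), paste(res$resno, res$ins))
  ok <- !is.na(idx)
  m[idx[ok], ] <- as.matrix(sub[ok, c("x", "y", "z")])
  m
}

#' Flag residues with incomplete backbones
#'
#' @param s an \code{\link{nr_structure}}.
#' @return data.frame of residues with a logical \code{complete} column
#'   (TRUE when N, CA, C and O are all present).
#' @export
backbone_completeness <- function(s) {
  res <- residue_table(s)
  res$complete <- vapply(seq_len(nrow(res)), function(i) {
    sub <- s[s$chain == res$chain[i] & s$resno == res$resno[i] &
             s$ins == res$ins[i], , drop = FALSE]
    all(c("N", "CA", "C", "O") %in% sub$elety)
  }, logical(1))
  res
}

# Apply a rigid motion (function on n x 3 matrices) to all atoms.
transform_structure <- function(s, f) {
  xyz <- f(as.matrix(s[, c("x", "y", "z")]))
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}
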