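# Minimal mmCIF _atom_site reader: parses the atom_site loop only (the
# part this package consumes), first model only. Quoted tokens and the
# '.'/'?' null markers are handled.
read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  # locate the loop_ whose field block is _atom_site.*
  i <- 1L; n <- length(lines)
  fields <- character(0); data_start <- NA_integer_
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; fl <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        fl <- c(fl, trimws(lines[j])); j <- j + 1L
      }
      if (length(fl) && all(grepl("^_atom_site\\.", fl))) {
        fields <- sub("^_atom_site\\.", "", fl)
        data_start <- j
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(fields)) stop("no _atom_site loop in ", path)
  rows <- list()
  i <- data_start
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^\\s*(loop_|_|data_|#)", ln) || !nzchar(trimws(ln))) break
    toks <- scan(text = ln, what = "character", quiet = TRUE)
    if (length(toks) == length(fields)) rows[[length(rows) + 1L]] <- toks
    i <- i + 1L
  }
  if (!length(rows)) stop("empty _atom_site loop in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(a, b = NULL) {
    v <- if (a %in% fields) m[, a] else if (!is.null(b) && b %in% fields) m[, b]
         else rep(NA_character_, nrow(m))
    v[v %in% c(".", "?")] <- ""
    v
  }
  model <- get("pdbx_PDB_model_num")
  keep <- if (all(model == "")) rep(TRUE, nrow(m)) else model == model[model != ""][1]
  grp <- get("group_PDB")
  if (any(grp != "")) keep <- keep & grp %in% c("ATOM", "HETATM")
  data.frame(
    chain = get("auth_asym_id", "label_asym_id")[keep],
    resno = as.integer(get("auth_seq_id", "label_seq_id")[keep]),
    ins = get("pdbx_PDB_ins_code")[keep],
    resid = get("auth_comp_id", "label_comp_id")[keep],
    elety = get("auth_atom_id", "label_atom_id")[keep],
    elesy = toupper(get("type_symbol")[keep]),
    alt = get("label_alt_id")[keep],
    occ = suppressWarnings(as.numeric(get("occupancy")[keep])),
    x = as.numeric(get("Cartn_x")[keep]),
    y = as.numeric(get("Cartn_y")[keep]),
    z = as.numeric(get("Cartn_z")[keep]),
    stringsAsFactors = FALSE)
}
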