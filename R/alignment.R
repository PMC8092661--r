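#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Clustal. Sequences are case-normalised to upper case and
#' both \code{'.'} and \code{'-'} are unified as the gap character \code{'-'}.
#' Columns are 1-based throughout the package.
#'
#' @param path file path.
#' @param format \code{"fasta"}, \code{"clustal"} or \code{"auto"}.
#' @return object of class \code{nr_alignment}: list with \code{labels},
#'   \code{seqs} (named character vector, equal lengths), \code{ncol}.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(ma)
  }
  nr_alignment(seqs)
}

#' Construct an alignment from named sequences
#' @param seqs named character vector of gapped sequences.
#' @return an \code{nr_alignment}.
#' @export
nr_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all alignment rows must be labelled")
  if (anyDuplicated(names(seqs)))
    stop("duplicate row labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("ragged alignment; offending rows: ",
         paste(names(seqs)[lens != max(lens)], collapse = ", "))
  structure(list(labels = names(seqs), seqs = seqs, ncol = unname(lens[1])),
            class = "nr_alignment")
}

#' @export
print.nr_alignment <- function(x, ...) {
  cat("<nr_alignment> ", length(x$seqs), " rows x ", x$ncol, " columns\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#' @param aln an \code{nr_alignment}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$labels), aln$seqs)), path)
  invisible(path)
}

MOTIF_VARIANTS <- data.frame(
  variant = c("RxxxE", "KxxxE", "QxxxE", "RxxxxxxE"),
  basic = c("R", "K", "Q", "R"),
  spacing = c(4L, 4L, 4L, 7L),
  stringsAsFactors = FALSE)

#' Scan alignment rows for the RxxxE motif and its variants
#'
#' The scan is gap-aware: pattern spacing is counted over non-gap residues,
#' so a motif interrupted by gap columns is still recognised. At a shared
#' basic-residue anchor the canonical RxxxE takes precedence over the
#' degraded variants (KxxxE, QxxxE, RxxxxxxE, in that order). Hits are
#' reported non-overlapping, left to right. Both motif columns must fall
#' inside \code{window}.
#'
#' @param aln an \code{nr_alignment}.
#' @param window c(start column, end column), 1-based inclusive; NULL for
#'   the full width.
#' @param variants subset of \code{c("RxxxE","KxxxE","QxxxE","RxxxxxxE")}.
#' @return data.frame: \code{taxon}, \code{basic_col}, \code{acidic_col}
#'   (alignment columns), \code{variant}.
#' @export
scan_motif <- function(aln, window = NULL,
                       variants = MOTIF_VARIANTS$variant) {
  stopifnot(inherits(aln, "nr_alignment"))
  if (is.null(window)) window <- c(1L, aln$ncol)
  if (window[1] > window[2] || window[1] < 1 || window[2] > aln$ncol)
    stop("empty or out-of-range window")
  vdef <- MOTIF_VARIANTS[MOTIF_VARIANTS$variant %in% variants, , drop = FALSE]
  if (!nrow(vdef)) stop("no known variants requested")
  hits <- list()
  for (tx in aln$labels) {
    chars <- strsplit(aln$seqs[[tx]], "")[[1]]
    cols <- which(chars != "-")            # alignment column of each residue
    res <- chars[cols]
    n <- length(res)
    i <- 1L
    while (i <= n) {
      found <- NULL
      for (v in seq_len(nrow(vdef))) {
        j <- i + vdef$spacing[v]
        if (j <= n && res[i] == vdef$basic[v] && res[j] == "E" &&
            cols[i] >= window[1] && cols[j] <= window[2]) {
          found <- data.frame(taxon = tx, basic_col = cols[i],
                              acidic_col = cols[j], variant = vdef$variant[v],
                              stringsAsFactors = FALSE)
          break                            # canonical-first precedence
        }
      }
      if (!is.null(found)) {
        hits[[length(hits) + 1L]] <- found
        i <- i + vdef$spacing[v] + 1L      # non-overlapping
      } else i <- i + 1L
    }
  }
  if (!length(hits))
    return(data.frame(taxon = character(), basic_col = integer(),
                      acidic_col = integer(), variant = character()))
  do.call(rbind, hits)
}

#' Generate an alignment with planted motif variants
#'
#' Background columns are drawn uniformly from the amino acids excluding
#' \{R, K, Q, E\} so that no spurious motif can arise; planted spans spell the
#' requested variant exactly (basic residue at the stated column, E at the
#' variant spacing).
#'
#' @param n_rows,n_cols alignment dimensions.
#' @param plants data.frame with columns \code{row}, \code{col} (column of
#'   the basic residue) and \code{variant}; NULL for none.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @return an \code{nr_alignment} with rows \code{"seq1"}..\code{"seqN"}.
#' @export
make_planted_alignment <- function(n_rows, n_cols, plants = NULL, seed = 1L) {
  background <- setdiff(strsplit("ACDFGHILMNPSTVWY", "")[[1]], character(0))
  set.seed(seed)
  m <- matrix(sample(background, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
  if (!is.null(plants) && nrow(plants)) {
    stopifnot(all(c("row", "col", "variant") %in% names(plants)))
    vdef <- MOTIF_VARIANTS[match(plants$variant, MOTIF_VARIANTS$variant), ]
    if (anyNA(vdef$variant)) stop("unknown variant label")
    ends <- plants$col + vdef$spacing
    if (any(ends > n_cols)) stop("planted span does not fit within n_cols")
    for (r in unique(plants$row)) {
      p <- which(plants$row == r)
      iv <- cbind(plants$col[p], ends[p])
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping plants in row ", r)
    }
    for (p in seq_len(nrow(plants))) {
      m[plants$row[p], plants$col[p]] <- vdef$basic[p]
      m[plants$row[p], ends[p]] <- "E"
    }
  }
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- paste0("seq", seq_len(n_rows))
  nr_alignment(seqs)
}
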