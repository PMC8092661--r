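#' Default class I / class II dimerization marker definition
#'
#' Marker residues in the Brelivet generic numbering that separate class I
#' nuclear receptors (monomers / homodimers) from class II receptors
#' (RXR heterodimer partners): E5, W40, K/R55, R/K93 and R105 for class I;
#' E/D42, R62 and H/R/K90 for class II; E50 and R105 universally conserved.
#' R105 appears both as a class I marker and as universally conserved; it is
#' treated as universal and additionally counted toward class I audits (its
#' absence counts against class I, matching the published SpNR2 audit).
#'
#' @return data.frame with columns \code{position} (Brelivet number),
#'   \code{allowed} (string of allowed 1-letter codes) and \code{class}
#'   (\code{"I"}, \code{"II"} or \code{"universal"}).
#' @export
default_marker_definition <- function() {
  data.frame(
    position = c(5L, 40L, 55L, 93L, 42L, 62L, 90L, 50L, 105L),
    allowed = c("E", "W", "KR", "RK", "ED", "R", "HRK", "E", "R"),
    class = c("I", "I", "I", "I", "II", "II", "II",
              "universal", "universal"),
    stringsAsFactors = FALSE)
}

#' Default Brelivet-position to alignment-column map
#'
#' The packaged residue-mapping table anchors Brelivet positions 40, 42, 50,
#' 61, 62, 93, 100, 105 and 106 to generic alignment positions; 5, 55 and 90
#' have no anchored column and need a user-supplied mapping.
#'
#' @return named integer vector, names are Brelivet positions.
#' @export
default_brelivet_map <- function() {
  c("40" = 109L, "42" = 111L, "50" = 220L, "61" = 262L, "62" = 263L,
    "93" = 309L, "100" = 316L, "105" = 321L, "106" = 322L)
}

#' Audit class I / class II markers on one alignment row
#'
#' A marker is present when the row's residue at the mapped column is in the
#' marker's allowed set. The verdict is \code{"class I"} or \code{"class II"}
#' when exactly that class is complete; \code{"outlier"} when neither class
#' is complete but the better class is broken by at most 2 missing markers;
#' \code{"undetermined"} otherwise (including the ambiguous case of both
#' classes complete). Universal markers are audited and reported but decide
#' no class; R105 also counts toward the class I tally.
#'
#' @param row a single gapped sequence string indexed by alignment column,
#'   or a named character vector (names = alignment columns).
#' @param def marker definition, see \code{\link{default_marker_definition}}.
#' @param position_map named integer vector Brelivet position -> alignment
#'   column; defaults to \code{\link{default_brelivet_map}}. Markers at
#'   unmapped positions are skipped with one warning.
#' @return list of class \code{marker_report}: per-marker table
#'   (\code{markers}), counts per class, \code{verdict}, and
#'   \code{skipped} positions.
#' @export
audit_class_markers <- function(row, def = default_marker_definition(),
                                position_map = default_brelivet_map()) {
  residue_at <- if (length(row) == 1L && is.null(names(row))) {
    chars <- strsplit(row, "")[[1]]
    function(col) if (col <= length(chars)) chars[col] else NA_character_
  } else {
    function(col) {
      v <- row[as.character(col)]
      if (length(v)) unname(v) else NA_character_
    }
  }
  mapped <- as.character(def$position) %in% names(position_map)
  skipped <- unique(def$position[!mapped])
  if (length(skipped))
    warning("markers at unmapped Brelivet positions skipped: ",
            paste(skipped, collapse = ", "))
  def <- def[mapped, , drop = FALSE]
  def$column <- unname(position_map[as.character(def$position)])
  def$residue <- vapply(def$column, residue_at, character(1))
  if (anyNA(def$residue))
    stop("row does not cover mapped column(s): ",
         paste(def$column[is.na(def$residue)], collapse = ", "))
  def$present <- mapply(function(res, allowed)
    res %in% strsplit(allowed, "")[[1]], def$residue, def$allowed)
  tally <- function(cl) {
    sub <- def[def$class == cl, , drop = FALSE]
    if (cl == "I") {                     # R105 counts toward class I too
      uni <- def[def$class == "universal" & def$position == 105L, , drop = FALSE]
      sub <- rbind(sub, uni)
    }
    c(total = nrow(sub), present = sum(sub$present))
  }
  tI <- tally("I"); tII <- tally("II"); tU <- tally("universal")
  missI <- tI["total"] - tI["present"]
  missII <- tII["total"] - tII["present"]
  completeI <- missI == 0 && tI["total"] > 0
  completeII <- missII == 0 && tII["total"] > 0
  verdict <- if (completeI && completeII) "undetermined"
             else if (completeI) "class I"
             else if (completeII) "class II"
             else if (min(missI, missII) <= 2) "outlier"
             else "undetermined"
  structure(list(markers = def,
                 counts = rbind(`I` = tI, `II` = tII, universal = tU),
                 missing_I = unname(missI), missing_II = unname(missII),
                 verdict = verdict, skipped = skipped),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat("<marker_report> verdict:", x$verdict,
      sprintf(" (class I %d/%d, class II %d/%d, universal %d/%d)\n",
              x$counts["I", "present"], x$counts["I", "total"],
              x$counts["II", "present"], x$counts["II", "total"],
              x$counts["universal", "present"], x$counts["universal", "total"]))
  invisible(x)
}
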