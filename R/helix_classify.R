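#' Per-residue helix classification from hydrogen-bond patterns
#'
#' DSSP-style n-turn logic. A k-turn starts at residue i when the donor at
#' i + k bonds back to the acceptor C=O of residue i (offsets k = 3, 4, 5 for
#' 3-10, alpha and pi helices). Two consecutive k-turns (at i - 1 and i) make
#' residues i .. i + k - 1 part of a k-helix. Overlaps are resolved with
#' priority pi > alpha > three_ten (classic DSSP's alpha-first priority
#' systematically under-reports pi-bulges, the very feature of interest
#' here; the order is configurable). Residues in an isolated single turn are
#' labelled \code{"turn"}, everything else \code{"coil"}.
#'
#' @param s structure the bonds were computed on.
#' @param hbonds output of \code{\link{compute_hbonds_ks}}.
#' @param priority class precedence on overlap, first wins.
#' @return data.frame, one row per residue: \code{chain}, \code{resno},
#'   \code{resid}, \code{class} in \{pi, alpha, three_ten, turn, coil\}, and
#'   logical flags \code{acc3}, \code{acc4}, \code{acc5} (residue accepts a
#'   bond from offset k) and \code{don3}, \code{don4}, \code{don5}.
#' @export
assign_helix_types <- function(s, hbonds,
                               priority = c("pi", "alpha", "three_ten")) {
  stopifnot(inherits(s, "nr_structure"))
  stopifnot(setequal(priority, c("pi", "alpha", "three_ten")))
  offsets <- c(three_ten = 3L, alpha = 4L, pi = 5L)
  out <- list()
  for (ch in unique(s$chain[s$resid != "HOH"])) {
    res <- residue_table(s, ch)
    n <- nrow(res)
    hb <- hbonds[hbonds$chain == ch, , drop = FALSE]
    turn <- sapply(c(3L, 4L, 5L), function(k) {
      t <- rep(FALSE, n)
      acc <- hb$acceptor[hb$offset == k]
      t[acc[acc + k <= n]] <- TRUE
      t
    })
    colnames(turn) <- c("3", "4", "5")
    cls <- rep("coil", n)
    # Two consecutive k-turns at (i-1, i) paint residues i .. i+k-2: one
    # residue tighter than classic DSSP at the C-terminal end, which keeps
    # the assignment centred on the residues whose dihedrals are helical
    # rather than on the bracketing donors. Lowest priority painted first so
    # higher priorities overwrite.
    for (cl in rev(priority)) {
      k <- offsets[[cl]]
      tk <- turn[, as.character(k)]
      starts <- which(tk & c(FALSE, tk[-n]))
      for (i in starts) cls[i:min(n, i + k - 2L)] <- cl
    }
    # residues inside any isolated single turn -> "turn"
    for (k in c(3L, 4L, 5L)) {
      for (i in which(turn[, as.character(k)])) {
        span <- i:min(n, i + k)
        span <- span[cls[span] == "coil"]
        cls[span] <- "turn"
      }
    }
    flags <- data.frame(
      acc3 = turn[, "3"], acc4 = turn[, "4"], acc5 = turn[, "5"],
      don3 = seq_len(n) %in% (which(turn[, "3"]) + 3L),
      don4 = seq_len(n) %in% (which(turn[, "4"]) + 4L),
      don5 = seq_len(n) %in% (which(turn[, "5"]) + 5L))
    out[[length(out) + 1L]] <- cbind(
      data.frame(chain = ch, resno = res$resno, resid = res$resid,
                 class = cls, stringsAsFactors = FALSE), flags)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate pi-turns (pi-bulges) in a helix assignment
#'
#' Maximal contiguous pi-classified stretches are reported as pi-turns. A
#' span flanked by alpha helix on both sides is a canonical pi-turn
#' (\code{flanked = TRUE}); spans touching a chain terminus or coil are
#' flagged \code{"unflanked"}. The bulge residue is the span residue whose CA
#' lies farthest from the local helix axis, fitted through the CA atoms of up
#' to four flanking alpha residues on each side (falling back to the span
#' itself when no flank exists).
#'
#' @param assign output of \code{\link{assign_helix_types}}.
#' @param s the structure.
#' @return data.frame: \code{chain}, \code{first_resno}, \code{last_resno},
#'   \code{bulge_resno}, \code{bulge_dist} (Angstroms off-axis),
#'   \code{flanked}, \code{weak} (single isolated offset-5 candidate).
#' @export
detect_pi_turns <- function(assign, s) {
  out <- list()
  for (ch in unique(assign$chain)) {
    a <- assign[assign$chain == ch, , drop = FALSE]
    n <- nrow(a)
    CA <- atom_coords(s, ch, "CA")
    is_pi <- a$class == "pi"
    r <- rle(is_pi)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- data.frame(start = starts[r$values], end = ends[r$values])
    # weak candidates: isolated offset-5 acceptor inside alpha context,
    # not already part of a pi span
    weak_at <- which(a$acc5 & a$class == "alpha")
    if (length(weak_at))
      spans <- rbind(cbind(spans, weak = FALSE),
                     data.frame(start = weak_at, end = weak_at, weak = TRUE))
    else if (nrow(spans)) spans$weak <- FALSE
    if (!nrow(spans)) next
    for (si in seq_len(nrow(spans))) {
      i0 <- spans$start[si]; i1 <- spans$end[si]
      left <- if (i0 > 1) a$class[i0 - 1] else NA
      right <- if (i1 < n) a$class[i1 + 1] else NA
      flanked <- identical(left, "alpha") && identical(right, "alpha")
      lf <- i0 - 1; flank_idx <- integer()
      while (lf >= 1 && a$class[lf] == "alpha" && length(flank_idx) < 4) {
        flank_idx <- c(flank_idx, lf); lf <- lf - 1
      }
      rf <- i1 + 1; cnt <- 0
      while (rf <= n && a$class[rf] == "alpha" && cnt < 4) {
        flank_idx <- c(flank_idx, rf); rf <- rf + 1; cnt <- cnt + 1
      }
      axis_idx <- if (length(flank_idx) >= 3) flank_idx else i0:i1
      axis_pts <- CA[axis_idx, , drop = FALSE]
      axis_pts <- axis_pts[stats::complete.cases(axis_pts), , drop = FALSE]
      span_idx <- i0:i1
      if (nrow(axis_pts) >= 2 && !anyNA(CA[span_idx, ])) {
        d <- dist_to_axis(CA[span_idx, , drop = FALSE], axis_pts)
        b <- span_idx[which.max(d)]
        bd <- max(d)
      } else {
        b <- span_idx[1]; bd <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, first_resno = a$resno[i0], last_resno = a$resno[i1],
        bulge_resno = a$resno[b], bulge_dist = bd,
        flanked = flanked, weak = spans$weak[si], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), first_resno = integer(),
                      last_resno = integer(), bulge_resno = integer(),
                      bulge_dist = numeric(), flanked = logical(),
                      weak = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
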