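# Independent oracles used across the suite. Each is written against the
# definitions directly (brute force / enumeration / closed form), sharing no
# code path with the implementation it checks.

# --- DSSP-style geometric classifier --------------------------------------
# Hydrogen bond: O(j)...N(j+k) within 3.5 A with a C-O...N angle above 130
# degrees (rejecting the short but bent O..N approaches inherent to helical
# geometry). A residue is classified k-helical when it lies strictly inside
# at least one offset-k bond; priority pi > alpha > three_ten.
oracle_classes <- function(s, chain = "A") {
  a <- as.data.frame(s)
  res <- unique(a[a$resid != "HOH" & a$chain == chain, c("resno", "ins")])
  n <- nrow(res)
  get <- function(el) {
    m <- matrix(NA_real_, n, 3)
    sub <- a[a$chain == chain & a$elety == el, ]
    m[match(sub$resno, res$resno), ] <- as.matrix(sub[, c("x", "y", "z")])
    m
  }
  N <- get("N"); O <- get("O"); C <- get("C")
  cov <- matrix(0L, n, 3); colnames(cov) <- c("3", "4", "5")
  for (k in 3:5) for (j in seq_len(max(0, n - k))) {
    if (anyNA(O[j, ]) || anyNA(N[j + k, ]) || anyNA(C[j, ])) next
    d <- sqrt(sum((O[j, ] - N[j + k, ])^2))
    v1 <- C[j, ] - O[j, ]; v2 <- N[j + k, ] - O[j, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (d <= 3.5 && ang > 130)
      cov[(j + 1):(j + k - 1), as.character(k)] <-
        cov[(j + 1):(j + k - 1), as.character(k)] + 1L
  }
  cls <- rep("other", n)
  cls[cov[, "3"] > 0] <- "three_ten"
  cls[cov[, "4"] > 0] <- "alpha"
  cls[cov[, "5"] > 0] <- "pi"
  cls
}

# Maximal runs of `what` in a class vector: matrix of (start, end) rows.
class_spans <- function(cls, what) {
  r <- rle(cls %in% what)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  cbind(start = s[r$values], end = e[r$values])
}

# --- likelihood oracles ----------------------------------------------------
# Exhaustive enumeration over all internal-node state assignments; uses
# ape::matexpo, not the package's transition_matrix.
enum_loglik <- function(tree, states, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    ape::matexpo(model$Q * tree$edge.length[e]))
  tip_idx <- states[tree$tip.label]
  k <- model$k
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internal)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_full <- integer(nn)
    assign_full[internal] <- as.integer(grid[g, ])
    like <- model$pi[assign_full[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      if (c <= ntip) {
        sc <- tip_idx[c]
        prob <- if (is.na(sc)) 1 else P[[e]][assign_full[p], sc]
      } else prob <- P[[e]][assign_full[p], assign_full[c]]
      like <- like * prob
    }
    tot <- tot + like
  }
  log(tot)
}

# Per-internal-node marginal posteriors by the same enumeration.
enum_marginals <- function(tree, states, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    ape::matexpo(model$Q * tree$edge.length[e]))
  tip_idx <- states[tree$tip.label]
  k <- model$k
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(internal)))
  acc <- matrix(0, length(internal), k)
  for (g in seq_len(nrow(grid))) {
    assign_full <- integer(nn)
    assign_full[internal] <- as.integer(grid[g, ])
    like <- model$pi[assign_full[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      if (c <= ntip) {
        sc <- tip_idx[c]
        prob <- if (is.na(sc)) 1 else P[[e]][assign_full[p], sc]
      } else prob <- P[[e]][assign_full[p], assign_full[c]]
      like <- like * prob
    }
    for (vi in seq_along(internal))
      acc[vi, assign_full[internal[vi]]] <- acc[vi, assign_full[internal[vi]]] + like
  }
  acc / rowSums(acc)
}

# Expected number of real transitions on one branch conditional on the
# endpoint pair (a, b) over time t:
#   E[N | a->b] = sum_{i != j} q_ij  Int_0^t P_ai(s) P_jb(t - s) ds / P_ab(t)
# computed by numerical integration with ape::matexpo.
expected_transitions_oracle <- function(Q, a, b, t) {
  k <- nrow(Q)
  pab <- ape::matexpo(Q * t)[a, b]
  tot <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || Q[i, j] <= 0) next
    f <- Vectorize(function(s) ape::matexpo(Q * s)[a, i] * ape::matexpo(Q * (t - s))[j, b])
    tot <- tot + Q[i, j] * stats::integrate(f, 0, t, rel.tol = 1e-9)$value
  }
  tot / pab
}

# Exhaustive small-parsimony minimum over all internal labelings.
enum_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  lv <- sort(unique(as.character(states)))
  tip_lab <- match(as.character(states[tree$tip.label]), lv)
  grid <- do.call(expand.grid, rep(list(seq_along(lv)), length(internal)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- tip_lab
    lab[internal] <- as.integer(grid[g, ])
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# Brute-force motif scan of a degapped sequence (left-to-right,
# non-overlapping, canonical-first at an anchor).
brute_scan <- function(seq_nogap) {
  defs <- list(RxxxE = c("R", 4L), KxxxE = c("K", 4L),
               QxxxE = c("Q", 4L), RxxxxxxE = c("R", 7L))
  res <- strsplit(seq_nogap, "")[[1]]
  out <- list(); i <- 1L
  while (i <= length(res)) {
    hit <- NULL
    for (v in names(defs)) {
      sp <- as.integer(defs[[v]][2])
      if (i + sp <= length(res) && res[i] == defs[[v]][1] && res[i + sp] == "E") {
        hit <- data.frame(pos = i, variant = v); break
      }
    }
    if (!is.null(hit)) { out[[length(out) + 1L]] <- hit; i <- i + sp + 1L }
    else i <- i + 1L
  }
  if (!length(out)) data.frame(pos = integer(), variant = character())
  else do.call(rbind, out)
}

# Small random rooted tree with branch lengths, for enumeration tests.
random_small_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1.5)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}
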