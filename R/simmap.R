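# Unconditional forward simulation of the CTMC from `state` over time `t`.
# Returns list(times, from, to, end): jump times are offsets in (0, t).
sim_path_forward <- function(Q, state, t) {
  times <- numeric(0); from <- integer(0); to <- integer(0)
  now <- 0; s <- state
  repeat {
    r <- -Q[s, s]
    if (r <= 0) break
    now <- now + stats::rexp(1, r)
    if (now >= t) break
    j <- sample.int(ncol(Q), 1, prob = Q[s, ] * (seq_len(ncol(Q)) != s))
    times <- c(times, now); from <- c(from, s); to <- c(to, j)
    s <- j
  }
  list(times = times, from = from, to = to, end = s)
}

# Sample a path conditional on endpoints (a -> b over t). Nielsen-style
# rejection first (with the first jump forced when a != b), then an exact
# uniformization sampler after `max_reject` failed attempts.
sample_branch_path <- function(model, a, b, t, max_reject = 1000L) {
  Q <- model$Q; k <- model$k
  if (t <= 0) {
    if (a != b) stop("inconsistent sample: differing endpoints on a zero-length branch")
    return(list(times = numeric(0), from = integer(0), to = integer(0)))
  }
  r_a <- -Q[a, a]
  if (r_a <= 0 && a != b) stop("inconsistent sample: absorbing start, differing endpoints")
  for (try in seq_len(max_reject)) {
    if (a == b) {
      p <- sim_path_forward(Q, a, t)
      if (p$end == b) return(p[c("times", "from", "to")])
    } else {
      # condition the first jump to occur before t
      u <- stats::runif(1)
      tau <- -log(1 - u * (1 - exp(-r_a * t))) / r_a
      j <- sample.int(k, 1, prob = Q[a, ] * (seq_len(k) != a))
      rest <- sim_path_forward(Q, j, t - tau)
      if (rest$end == b)
        return(list(times = c(tau, tau + rest$times),
                    from = c(a, rest$from), to = c(j, rest$to)))
    }
  }
  uniformization_path(model, a, b, t)
}

# Exact endpoint-conditioned path via uniformization.
uniformization_path <- function(model, a, b, t) {
  Q <- model$Q; k <- model$k
  mu <- max(-diag(Q))
  if (mu <= 0) {
    if (a != b) stop("inconsistent sample: zero rate matrix, differing endpoints")
    return(list(times = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- diag(k) + Q / mu
  pab <- transition_matrix(model, t)[a, b]
  if (pab <= 0) stop("inconsistent sample: endpoint pair has probability 0")
  # P(N = n | endpoints) ~ dpois(n, mu t) R^n[a,b] / pab
  Rpow <- list(diag(k))
  probs <- numeric(0); cum <- 0; n <- 0
  target <- 1 - 1e-12
  while (cum / pab < target && n < 10000L) {
    pn <- stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b]
    probs <- c(probs, pn); cum <- cum + pn
    n <- n + 1L
    Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  }
  nj <- sample.int(length(probs), 1, prob = probs) - 1L
  if (nj == 0L) return(list(times = numeric(0), from = integer(0), to = integer(0)))
  # discrete bridge over the jump chain
  ss <- integer(nj + 1L); ss[1] <- a; ss[nj + 1L] <- b
  if (nj > 1) for (m in 2:nj) {
    w <- R[ss[m - 1L], ] * Rpow[[nj - m + 2L]][, b]
    ss[m] <- sample.int(k, 1, prob = w)
  }
  tms <- sort(stats::runif(nj, 0, t))
  keep <- ss[-1] != ss[-(nj + 1L)]         # drop virtual (self) jumps
  list(times = tms[keep], from = ss[-(nj + 1L)][keep], to = ss[-1][keep])
}

#' Sample stochastic character maps
#'
#' Joint ancestral states are drawn from their exact conditional
#' distribution (root-to-tip sampling over the pruning partials); each
#' branch path is then sampled conditional on its endpoints, by rejection
#' sampling with an exact uniformization fallback. Deterministic given
#' \code{seed}.
#'
#' @inheritParams pruning_loglik
#' @param n number of histories to sample (>= 1).
#' @param seed RNG seed.
#' @return list of class \code{simmap_samples}: \code{tree}, \code{model},
#'   \code{node_states} (n x nodes matrix), \code{paths} (per sample, per
#'   node-below-branch: list(times, from, to)), \code{transitions}
#'   (n x k x k transition-count array).
#' @export
sample_stochastic_maps <- function(tree, states, model, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  up <- pruning_pass(tree, states, model)
  ti <- up$ti; k <- model$k; L <- up$L
  node_states <- matrix(NA_integer_, n, ti$nnode)
  trans <- array(0L, c(n, k, k))
  paths <- vector("list", n)
  root_w <- model$pi * L[ti$root, ]
  for (it in seq_len(n)) {
    st <- integer(ti$nnode)
    st[ti$root] <- sample.int(k, 1, prob = root_w)
    for (v in ti$preorder) {
      for (c in ti$children[[v]]) {
        w <- up$P[[c]][st[v], ] * L[c, ]
        st[c] <- sample.int(k, 1, prob = w)
      }
    }
    pth <- vector("list", ti$nnode)
    for (v in seq_len(ti$nnode)) {
      if (is.na(ti$elen[v])) next
      p <- sample_branch_path(model, st[ti$parent[v]], st[v], ti$elen[v])
      pth[[v]] <- p
      if (length(p$from))
        for (e in seq_along(p$from))
          trans[it, p$from[e], p$to[e]] <- trans[it, p$from[e], p$to[e]] + 1L
    }
    node_states[it, ] <- st
    paths[[it]] <- pth
  }
  structure(list(tree = tree, model = model, node_states = node_states,
                 paths = paths, transitions = trans, seed = seed),
            class = "simmap_samples")
}

#' Summarise stochastic maps
#'
#' Node state frequencies over the samples and the distribution of
#' per-transition-type counts (mean and quantiles), the reimplemented
#' equivalent of the usual simmap summary.
#'
#' @param samples a \code{\link{sample_stochastic_maps}} result.
#' @return list of class \code{simmap_summary}: \code{node_freq} (nodes x
#'   states, rows sum to 1), \code{transition_mean} (k x k),
#'   \code{transition_quantiles}, \code{n}.
#' @export
summarize_maps <- function(samples) {
  stopifnot(inherits(samples, "simmap_samples"))
  k <- samples$model$k
  ns <- samples$node_states
  n <- nrow(ns)
  freq <- t(apply(ns, 2, function(col) tabulate(col, k) / n))
  colnames(freq) <- samples$model$labels
  tm <- apply(samples$transitions, c(2, 3), mean)
  total <- apply(samples$transitions, 1, sum)
  structure(list(node_freq = freq, transition_mean = tm,
                 total_transitions_mean = mean(total),
                 transition_quantiles = stats::quantile(total, c(.025, .5, .975)),
                 n = n),
            class = "simmap_summary")
}
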