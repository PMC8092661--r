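#' Felsenstein pruning log-likelihood
#'
#' Postorder pass over the (possibly multifurcating) rooted tree; missing
#' tip states contribute all-ones partials (the conservative "coded as
#' unknown" policy), the root is combined with the model's prior. Partials
#' are rescaled per node, so the result is stable on large trees.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param states named integer vector (tip label -> state index in 1..k),
#'   NA or absent = missing.
#' @param model a \code{\link{rate_model}}.
#' @return natural-log likelihood (scalar).
#' @export
pruning_loglik <- function(tree, states, model) {
  up <- pruning_pass(tree, states, model)
  up$loglik
}

# Shared up-pass: returns per-node scaled partials, the per-branch
# transition matrices and the total log-likelihood.
pruning_pass <- function(tree, states, model) {
  ti <- tree_index(tree)
  k <- model$k
  tip_idx <- tip_state_index(tree, states, k)
  L <- matrix(1, ti$nnode, k)
  for (i in seq_len(ti$ntip))
    if (!is.na(tip_idx[i])) { L[i, ] <- 0; L[i, tip_idx[i]] <- 1 }
  P <- vector("list", ti$nnode)           # P along the branch above each node
  for (v in seq_len(ti$nnode))
    if (!is.na(ti$elen[v])) P[[v]] <- transition_matrix(model, ti$elen[v])
  logscale <- 0
  for (v in ti$postorder) {
    ch <- ti$children[[v]]
    if (!length(ch)) next
    part <- rep(1, k)
    for (c in ch) part <- part * as.vector(P[[c]] %*% L[c, ])
    m <- max(part)
    if (m <= 0) stop("zero likelihood at node ", v, " (impossible data?)")
    L[v, ] <- part / m
    logscale <- logscale + log(m)
  }
  lik <- sum(model$pi * L[ti$root, ])
  list(L = L, P = P, ti = ti, loglik = log(lik) + logscale)
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal posterior state probabilities by the standard
#' up/down message-passing scheme: the up pass collects subtree partials,
#' the down pass propagates the evidence outside each subtree; the root uses
#' the model's prior.
#'
#' @inheritParams pruning_loglik
#' @return matrix (internal nodes x k states) of posterior probabilities,
#'   row names are ape node numbers, each row sums to 1; attribute
#'   \code{loglik} carries the data log-likelihood.
#' @export
marginal_asr <- function(tree, states, model) {
  up <- pruning_pass(tree, states, model)
  ti <- up$ti; k <- model$k; L <- up$L
  down <- matrix(NA_real_, ti$nnode, k)
  down[ti$root, ] <- model$pi
  for (v in up$ti$preorder) {
    ch <- ti$children[[v]]
    if (length(ch) < 1) next
    # messages from each child subtree into v
    msg <- lapply(ch, function(c) as.vector(up$P[[c]] %*% L[c, ]))
    for (ci in seq_along(ch)) {
      c <- ch[ci]
      out <- down[v, ]
      for (cj in seq_along(ch)) if (cj != ci) out <- out * msg[[cj]]
      dmsg <- as.vector(t(up$P[[c]]) %*% out)
      sm <- sum(dmsg)
      down[c, ] <- if (sm > 0) dmsg / sm else dmsg
    }
  }
  internal <- (ti$ntip + 1L):ti$nnode
  post <- down[internal, , drop = FALSE] * L[internal, , drop = FALSE]
  post <- post / rowSums(post)
  rownames(post) <- internal
  colnames(post) <- model$labels
  attr(post, "loglik") <- up$loglik
  post
}
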