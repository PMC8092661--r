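#' Forward-simulate a discrete character on a tree
#'
#' Gillespie simulation along every branch under the model's rate matrix:
#' exponential waiting times with rate -Q[s,s], jumps to state j with
#' probability Q[s,j] / -Q[s,s]. The same generator the inference machinery
#' assumes, so simulate-under / fit-under experiments are exact.
#'
#' @param tree rooted \code{phylo}, branch lengths >= 0.
#' @param model a \code{\link{rate_model}}.
#' @param root_state state index, or \code{"prior"} to draw from the model's
#'   root prior.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return list of class \code{simulated_character}: \code{tree},
#'   \code{node_states} (by ape node number), \code{tip_states} (named by
#'   tip label), \code{events} (data.frame node, time, from, to: transitions
#'   on the branch above each node, times measured from the branch start),
#'   \code{model}, \code{seed}.
#' @export
simulate_character_evolution <- function(tree, model, root_state = "prior",
                                         seed = 1L) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(seed)
  ti <- tree_index(tree)
  k <- model$k
  st <- integer(ti$nnode)
  st[ti$root] <- if (identical(root_state, "prior"))
    sample.int(k, 1, prob = model$pi) else as.integer(root_state)
  if (st[ti$root] < 1 || st[ti$root] > k) stop("root state out of range")
  ev <- list()
  for (v in ti$preorder) {
    for (c in ti$children[[v]]) {
      p <- sim_path_forward(model$Q, st[v], ti$elen[c])
      st[c] <- p$end
      if (length(p$times))
        ev[[length(ev) + 1L]] <- data.frame(node = c, time = p$times,
                                            from = p$from, to = p$to)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(node = integer(), time = numeric(),
                            from = integer(), to = integer())
  tips <- st[seq_len(ti$ntip)]
  names(tips) <- tree$tip.label
  structure(list(tree = tree, node_states = st, tip_states = tips,
                 events = events, model = model, seed = seed),
            class = "simulated_character")
}
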