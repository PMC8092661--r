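#' Read a rooted tree from Newick text or file
#'
#' Wraps the ape parser with the validation the downstream character engine
#' needs: unique non-empty tip labels, finite non-negative branch lengths
#' (zero allowed), a single root. Multifurcations are allowed.
#'
#' @param x Newick string or path to a Newick file.
#' @return an \code{ape::phylo} tree.
#' @export
read_tree <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: parser returned nothing")
  if (any(is.na(tr$tip.label) | tr$tip.label == ""))
    stop("unlabeled tip in tree")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tr
}

#' Simulate a pure-birth tree scaled to unit depth
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed; output is deterministic given the seed.
#' @return ultrametric \code{phylo} tree of depth 1, tips \code{t1..tn}.
#' @export
make_random_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

# Internal traversal index shared by the likelihood/simulation code.
# Nodes use ape numbering: tips 1..ntip, root ntip+1.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  children <- vector("list", nn)
  parent <- integer(nn); parent[] <- NA_integer_
  elen <- numeric(nn); elen[] <- NA_real_
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    children[[p]] <- c(children[[p]], c)
    parent[c] <- p
    elen[c] <- tree$edge.length[e]
  }
  stack <- root; visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(visit)
  list(ntip = ntip, nnode = nn, root = root, children = children,
       parent = parent, elen = elen, postorder = post, preorder = visit)
}

# Map a named character vector of states onto tip indices; NA = missing.
tip_state_index <- function(tree, states, k) {
  out <- rep(NA_integer_, length(tree$tip.label))
  idx <- match(tree$tip.label, names(states))
  out[!is.na(idx)] <- states[idx[!is.na(idx)]]
  if (any(!is.na(out) & (out < 1L | out > k)))
    stop("state index out of range 1..", k)
  out
}
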