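#' Dollo loss count for a binary character
#'
#' Single origin, irreversible loss: assuming the character is present at
#' the root, the minimal number of presence-to-absence events covering all
#' absent tips equals the number of maximal clades whose (non-missing) tip
#' descendants are all absent; each loss is placed on the branch above the
#' highest such node. Tips with missing state are pruned first.
#'
#' @param tree rooted \code{phylo}.
#' @param states named vector over tips with values \code{"present"},
#'   \code{"absent"} or NA (alternatively 1/0/NA).
#' @param root_state must be \code{"present"} when any tip is present
#'   (a present tip under an absent root violates the Dollo premise).
#' @return integer loss count.
#' @export
dollo_loss_count <- function(tree, states, root_state = "present") {
  st <- normalize_binary_states(states)
  known <- names(st)[!is.na(st)]
  drop <- setdiff(tree$tip.label, known)
  if (length(drop)) {
    if (length(drop) >= length(tree$tip.label) - 1)
      stop("fewer than 2 tips with known state")
    tree <- ape::drop.tip(tree, drop)
  }
  present <- st[tree$tip.label] == "present"
  if (root_state != "present") {
    if (any(present)) stop("root state 'absent' with present tips violates the Dollo premise")
    return(0L)
  }
  if (!any(!present)) return(0L)
  ti <- tree_index(tree)
  all_abs <- logical(ti$nnode)
  all_abs[seq_len(ti$ntip)] <- !present
  for (v in ti$postorder) {
    ch <- ti$children[[v]]
    if (length(ch)) all_abs[v] <- all(all_abs[ch])
  }
  all_abs[ti$root] <- FALSE               # root declared present
  losses <- 0L
  for (v in seq_len(ti$nnode))
    if (v != ti$root && all_abs[v] && !all_abs[ti$parent[v]]) losses <- losses + 1L
  losses
}

#' Fitch (Hartigan) small-parsimony change count
#'
#' Minimum number of state changes on the rooted tree under unit costs;
#' multifurcations are handled by the Hartigan generalisation (at each node
#' keep the states attained by the maximal number of children; cost grows by
#' the number of children not attaining them). Tips with missing state are
#' pruned first.
#'
#' @param tree rooted \code{phylo}.
#' @param states named vector of tip states (any discrete labels; NA =
#'   missing).
#' @return integer minimum change count.
#' @export
fitch_parsimony <- function(tree, states) {
  st <- states[!is.na(states)]
  drop <- setdiff(tree$tip.label, names(st))
  if (length(drop)) {
    if (length(drop) >= length(tree$tip.label) - 1)
      stop("fewer than 2 tips with known state")
    tree <- ape::drop.tip(tree, drop)
  }
  lv <- sort(unique(as.character(st)))
  ti <- tree_index(tree)
  sets <- vector("list", ti$nnode)
  for (i in seq_len(ti$ntip))
    sets[[i]] <- as.character(st[tree$tip.label[i]])
  cost <- 0L
  for (v in ti$postorder) {
    ch <- ti$children[[v]]
    if (!length(ch)) next
    tab <- table(unlist(lapply(ch, function(c) unique(sets[[c]]))))
    mx <- max(tab)
    sets[[v]] <- names(tab)[tab == mx]
    cost <- cost + length(ch) - mx
  }
  cost
}

normalize_binary_states <- function(states) {
  st <- states
  if (is.numeric(st)) st <- ifelse(is.na(st), NA, ifelse(st > 0, "present", "absent"))
  st <- as.character(st)
  names(st) <- names(states)
  bad <- !is.na(st) & !st %in% c("present", "absent")
  if (any(bad)) stop("binary character expected: offending values ",
                     paste(unique(st[bad]), collapse = ", "))
  st
}
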