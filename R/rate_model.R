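#' Symmetric-rate continuous-time Markov model for a discrete character
#'
#' Builds a k-state rate matrix Q with symmetric off-diagonal rates
#' (q_ij = q_ji >= 0) and zero row sums, plus a root prior. A single rate
#' gives the equal-rates (ER) model; a vector of length k(k-1)/2 fills the
#' upper triangle column-wise (the SYM model).
#'
#' @param k number of states (>= 2).
#' @param rates scalar (ER) or upper-triangle vector (SYM), all >= 0.
#' @param prior \code{"equal"} (1/k, the default, matching the common
#'   stochastic-mapping default), \code{"stationary"} (identical to equal for
#'   a symmetric Q), or an explicit probability vector.
#' @param labels optional state labels (length k).
#' @return object of class \code{rate_model}: Q, prior \code{pi}, \code{k},
#'   \code{labels}, and a cached symmetric eigendecomposition.
#' @export
rate_model <- function(k, rates, prior = "equal", labels = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  np <- k * (k - 1L) / 2L
  if (length(rates) == 1L) rates <- rep(rates, np)
  if (length(rates) != np) stop("need 1 or ", np, " rates for k = ", k)
  if (any(rates < 0)) stop("rates must be >= 0")
  Q <- matrix(0, k, k)
  Q[upper.tri(Q)] <- rates
  Q <- Q + t(Q)
  diag(Q) <- -rowSums(Q)
  if (is.character(prior)) {
    prior <- match.arg(prior, c("equal", "stationary"))
    pi <- rep(1 / k, k)            # symmetric Q: stationary == uniform
  } else {
    if (length(prior) != k || any(prior < 0) || abs(sum(prior) - 1) > 1e-9)
      stop("prior must be a length-k probability vector")
    pi <- prior
  }
  if (is.null(labels)) labels <- paste0("state", seq_len(k))
  eig <- eigen(Q, symmetric = TRUE)
  structure(list(k = k, Q = Q, pi = pi, labels = labels,
                 eig = eig, rates = rates),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> k =", x$k, "states:", paste(x$labels, collapse = ", "), "\n")
  cat("rates:", paste(signif(x$rates, 4), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached eigendecomposition of the symmetric Q; rows sum
#' to 1 and P(0) is the identity.
#'
#' @param model a \code{\link{rate_model}}.
#' @param t branch length (>= 0).
#' @return k x k stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("t must be >= 0")
  V <- model$eig$vectors
  P <- V %*% (exp(model$eig$values * t) * t(V))
  P[P < 0] <- 0                           # clip eigen round-off
  P / rowSums(P)
}
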