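#' Maximum-likelihood rate estimation
#'
#' Maximises the pruning log-likelihood over non-negative rates. The ER
#' model is a bounded one-dimensional search; SYM optimises the
#' k(k-1)/2 free rates with L-BFGS-B on a log scale. Characters invariant
#' across tips sit at the q = 0 boundary and are returned with a warning
#' rather than an error.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param chars a named state vector (one character) or a list of named
#'   state vectors (independent characters sharing the model); the
#'   log-likelihood is summed over characters.
#' @param model_spec \code{"ER"} (single rate) or \code{"SYM"}.
#' @param k number of states; inferred from the data when NULL.
#' @param upper upper bound for each rate.
#' @param tol convergence tolerance of the bounded search.
#' @return list: \code{model} (fitted \code{\link{rate_model}}),
#'   \code{loglik}, \code{convergence} flag, \code{boundary} flag.
#' @export
fit_rates_ml <- function(tree, chars, model_spec = c("ER", "SYM"), k = NULL,
                         upper = 100, tol = 1e-8) {
  model_spec <- match.arg(model_spec)
  if (!is.list(chars)) chars <- list(chars)
  obs <- unlist(lapply(chars, function(x) x[!is.na(x)]))
  if (is.null(k)) k <- max(obs)
  k <- as.integer(k)
  loglik_at <- function(rates) {
    m <- rate_model(k, rates)
    sum(vapply(chars, function(st) pruning_loglik(tree, st, m), 0))
  }
  if (length(unique(obs)) < 2) {
    warning("all observed tips share one state: rate fixed at the 0 boundary")
    m0 <- rate_model(k, 0)
    return(list(model = m0, loglik = loglik_at(0),
                convergence = TRUE, boundary = TRUE))
  }
  if (model_spec == "ER") {
    opt <- stats::optimize(function(lq) -loglik_at(exp(lq)),
                           lower = log(1e-8), upper = log(upper), tol = tol)
    q <- exp(opt$minimum)
    m <- rate_model(k, q)
    list(model = m, loglik = -opt$objective, convergence = TRUE,
         boundary = q <= 1.5e-8 || q >= upper * 0.99)
  } else {
    np <- k * (k - 1L) / 2L
    start <- rep(log(0.5), np)
    opt <- stats::optim(start, function(lq) -loglik_at(exp(lq)),
                        method = "L-BFGS-B",
                        lower = log(1e-8), upper = log(upper),
                        control = list(factr = 1e4))
    rates <- exp(opt$par)
    list(model = rate_model(k, rates), loglik = -opt$value,
         convergence = opt$convergence == 0,
         boundary = any(rates <= 1.5e-8 | rates >= upper * 0.99))
  }
}
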