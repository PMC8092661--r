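test_that("Newick parsing validates labels, lengths and round trips", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  f <- tempfile(); ape::write.tree(tr, f)
  tr2 <- read_tree(f)
  expect_true(ape::all.equal.phylo(tr, tr2))
  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(suppressWarnings(read_tree("((A:1,B:1):1,C:2")),
               "malformed|unexpected")
  expect_error(read_tree("((A:1,B:-1):1,C:2);"), ">= 0")
})

test_that("transition matrices obey the closed forms", {
  m <- rate_model(2, 0.8)
  expect_equal(transition_matrix(m, 0), diag(2), tolerance = 1e-12)
  for (t in c(0.1, 0.5, 2, 7)) {
    P <- transition_matrix(m, t)
    expect_lt(abs(P[1, 1] - (1 + exp(-2 * 0.8 * t)) / 2), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
  # long-time limit: rows approach the stationary (uniform) distribution
  m3 <- rate_model(3, c(0.3, 0.9, 0.6))
  Pinf <- transition_matrix(m3, 200)
  expect_lt(max(abs(Pinf - 1 / 3)), 1e-8)
  expect_error(transition_matrix(m, -1), ">= 0")
})

test_that("pruning equals the closed form and handles degenerate rates", {
  q <- 0.7; t1 <- 0.4; t2 <- 1.1
  tr <- read_tree(sprintf("(A:%f,B:%f);", t1, t2))
  m <- rate_model(2, q)
  ll <- pruning_loglik(tr, c(A = 1L, B = 1L), m)
  P1 <- transition_matrix(m, t1); P2 <- transition_matrix(m, t2)
  expect_lt(abs(ll - log(sum(m$pi * P1[, 1] * P2[, 1]))), 1e-10)

  # rate 0, all tips one state, uniform prior over k: logL = log(1/k)
  for (k in 2:4) {
    m0 <- rate_model(k, 0)
    tr4 <- make_random_tree(6, seed = k)
    st <- stats::setNames(rep(1L, 6), tr4$tip.label)
    expect_equal(pruning_loglik(tr4, st, m0), log(1 / k), tolerance = 1e-12)
  }
  expect_error(pruning_loglik(tr, c(A = 1L, B = 5L), rate_model(2, 1)), "range")
})

test_that("pruning matches exhaustive enumeration on small trees", {
  set.seed(12)
  for (n in 3:5) for (k in 2:4) {
    tr <- random_small_tree(n, seed = n * 10 + k)
    m <- rate_model(k, stats::runif(k * (k - 1) / 2, 0.2, 1.5))
    st <- stats::setNames(sample.int(k, n, replace = TRUE), tr$tip.label)
    st[1] <- NA                                        # one missing tip
    expect_lt(abs(pruning_loglik(tr, st, m) - enum_loglik(tr, st, m)), 1e-10)
  }
  # multifurcating tree
  trm <- read_tree("((A:0.3,B:0.4,C:0.2):0.5,D:0.8,E:0.3);")
  m <- rate_model(2, 0.9)
  st <- c(A = 1L, B = 2L, C = 1L, D = 2L, E = 1L)
  expect_lt(abs(pruning_loglik(trm, st, m) - enum_loglik(trm, st, m)), 1e-10)
})

test_that("likelihood is invariant under re-rooting for the reversible model", {
  tr <- random_small_tree(6, seed = 4)
  m <- rate_model(3, c(0.4, 0.8, 0.3))
  st <- stats::setNames(sample.int(3, 6, replace = TRUE), tr$tip.label)
  ll <- pruning_loglik(tr, st, m)
  for (node in c(2, 4)) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[node],
                     resolve.root = TRUE)
    expect_lt(abs(pruning_loglik(tr2, st, m) - ll), 1e-8)
  }
})

test_that("marginal reconstruction matches the enumeration oracle", {
  set.seed(9)
  for (n in c(4, 5)) {
    tr <- random_small_tree(n, seed = n)
    k <- 3
    m <- rate_model(k, stats::runif(3, 0.2, 1.2))
    st <- stats::setNames(sample.int(k, n, replace = TRUE), tr$tip.label)
    post <- marginal_asr(tr, st, m)
    ref <- enum_marginals(tr, st, m)
    expect_lt(max(abs(post - ref)), 1e-9)
    expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  }
  # symmetric two-tip disagreement: root posterior is exactly (1/2, 1/2)
  tr2 <- read_tree("(A:0.6,B:0.6);")
  post2 <- marginal_asr(tr2, c(A = 1L, B = 2L), rate_model(2, 0.5))
  expect_equal(unname(post2[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # all tips one state with a small rate: root nearly certain
  tr3 <- make_random_tree(8, seed = 2)
  post3 <- marginal_asr(tr3, stats::setNames(rep(2L, 8), tr3$tip.label),
                        rate_model(2, 0.05))
  expect_gt(post3[1, 2], 0.99)
})

test_that("rate fitting finds a local optimum and flags boundaries", {
  tr <- make_random_tree(64, seed = 21)
  sim <- simulate_character_evolution(tr, rate_model(2, 0.9), "prior", seed = 5)
  fit <- fit_rates_ml(tr, sim$tip_states, "ER", k = 2)
  q <- fit$model$rates[1]
  ll <- function(qq) pruning_loglik(tr, sim$tip_states, rate_model(2, qq))
  expect_gte(fit$loglik + 1e-6, ll(2 * q))
  expect_gte(fit$loglik + 1e-6, ll(q / 2))
  expect_true(fit$convergence)

  expect_warning(f0 <- fit_rates_ml(tr, stats::setNames(rep(1L, 64), tr$tip.label),
                                    "ER", k = 2), "boundary")
  expect_true(f0$boundary)
  expect_equal(f0$model$rates[1], 0)

  # SYM fit recovers unequal rates to the right order on a large star-like tree
  tr2 <- make_random_tree(96, seed = 31)
  sim2 <- simulate_character_evolution(tr2, rate_model(3, c(1.2, 0.1, 0.7)),
                                       "prior", seed = 8)
  fs <- fit_rates_ml(tr2, sim2$tip_states, "SYM", k = 3)
  expect_equal(length(fs$model$rates), 3)
  expect_true(fs$convergence)
})

test_that("simmap samples are endpoint-consistent and reproducible", {
  tr <- make_random_tree(6, seed = 14)
  m <- rate_model(2, 0.8)
  st <- stats::setNames(c(1L, 1L, 2L, 1L, 2L, 1L), tr$tip.label)
  s1 <- sample_stochastic_maps(tr, st, m, n = 25, seed = 99)
  s2 <- sample_stochastic_maps(tr, st, m, n = 25, seed = 99)
  expect_identical(s1$node_states, s2$node_states)
  expect_identical(s1$transitions, s2$transitions)

  ti <- nrpiturn:::tree_index(tr)
  for (it in seq_len(25)) {
    stn <- s1$node_states[it, ]
    expect_identical(stn[seq_len(6)], unname(st))   # sampled tips match data
    for (v in seq_len(ti$nnode)) {
      if (is.na(ti$elen[v])) next
      p <- s1$paths[[it]][[v]]
      cur <- stn[ti$parent[v]]
      if (length(p$from)) {
        expect_true(all(diff(p$times) >= 0) && all(p$times < ti$elen[v] + 1e-12))
        for (e in seq_along(p$from)) {
          expect_equal(p$from[e], cur)
          cur <- p$to[e]
        }
      }
      expect_equal(cur, stn[v])                     # path ends at the node state
    }
    # parsimony lower-bounds every sampled history
    expect_gte(sum(s1$transitions[it, , ]), fitch_parsimony(tr, st))
  }
})

test_that("zero-rate maps carry zero transitions", {
  tr <- make_random_tree(5, seed = 3)
  st <- stats::setNames(rep(2L, 5), tr$tip.label)
  s <- sample_stochastic_maps(tr, st, rate_model(2, 0), n = 10, seed = 1)
  expect_true(all(s$transitions == 0))
  expect_true(all(s$node_states == 2L))
})

test_that("conditioned-branch transition counts match the uniformization oracle", {
  q <- 0.9; t <- 1.2; nmc <- 10000
  m <- rate_model(2, q)
  tr <- read_tree(sprintf("(A:%f,B:1e-9);", t))
  # forcing both tips and a tiny second branch pins the root state:
  # branch A is then an endpoint-conditioned 1 -> 1 path of length t
  st <- c(A = 1L, B = 1L)
  s <- sample_stochastic_maps(tr, st, m, n = nmc, seed = 42)
  counts <- apply(s$transitions, 1, sum)
  expected <- expected_transitions_oracle(m$Q, 1, 1, t)
  se <- stats::sd(counts) / sqrt(nmc)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("zero-length branches with differing endpoints are rejected", {
  m <- rate_model(2, 1)
  expect_error(nrpiturn:::sample_branch_path(m, 1, 2, 0), "inconsistent")
  p <- nrpiturn:::sample_branch_path(m, 1, 1, 0)
  expect_equal(length(p$times), 0)
})

test_that("map summaries aggregate frequencies and counts correctly", {
  tr <- make_random_tree(5, seed = 8)
  st <- stats::setNames(c(1L, 1L, 2L, 2L, 1L), tr$tip.label)
  m <- rate_model(2, 0.6)
  s <- sample_stochastic_maps(tr, st, m, n = 200, seed = 7)
  sm <- summarize_maps(s)
  expect_equal(unname(rowSums(sm$node_freq)), rep(1, nrow(sm$node_freq)),
               tolerance = 1e-12)
  expect_equal(sm$total_transitions_mean, mean(apply(s$transitions, 1, sum)))
  expect_equal(sm$n, 200)
})

test_that("Dollo loss counting handles the canonical cases", {
  tr <- read_tree("(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2);")
  all_p <- stats::setNames(rep("present", 6), letters[1:6])
  expect_equal(dollo_loss_count(tr, all_p), 0)

  one_cherry <- all_p; one_cherry[c("c", "d")] <- "absent"
  expect_equal(dollo_loss_count(tr, one_cherry), 1)

  two_sep <- all_p; two_sep[c("a", "e")] <- "absent"
  expect_equal(dollo_loss_count(tr, two_sep), 2)

  expect_error(dollo_loss_count(tr, all_p, root_state = "absent"), "Dollo")
  none <- stats::setNames(rep("absent", 6), letters[1:6])
  expect_equal(dollo_loss_count(tr, none, root_state = "absent"), 0)
})

test_that("Fitch equals exhaustive minimisation and bounds Dollo", {
  set.seed(44)
  for (n in 4:6) {
    tr <- random_small_tree(n, seed = n + 50)
    st <- stats::setNames(sample(c("present", "absent"), n, replace = TRUE),
                          tr$tip.label)
    expect_equal(fitch_parsimony(tr, st), enum_parsimony(tr, st))
  }
  # multistate, multifurcating
  trm <- read_tree("((A:1,B:1,C:1):1,(D:1,E:1):1);")
  stm <- c(A = "x", B = "y", C = "x", D = "z", E = "z")
  expect_equal(fitch_parsimony(trm, stm), enum_parsimony(trm, stm))

  # Dollo needs at least as many events as Fitch on 100 fuzz characters
  tr <- make_random_tree(12, seed = 9)
  for (rep in 1:100) {
    st <- stats::setNames(sample(c("present", "absent"), 12, replace = TRUE,
                                 prob = c(0.6, 0.4)), tr$tip.label)
    if (!any(st == "absent")) next
    dl <- dollo_loss_count(tr, st)
    expect_gte(dl, fitch_parsimony(tr, st))
    expect_lte(dl, sum(st == "absent"))
  }
})

test_that("ER fits agree with an independent Mk implementation", {
  tr <- make_random_tree(24, seed = 5)
  sim <- simulate_character_evolution(tr, rate_model(2, 0.7), "prior", seed = 2)
  x <- stats::setNames(c("a", "b")[sim$tip_states], names(sim$tip_states))
  fm <- phytools::fitMk(tr, x, model = "ER")
  mine <- fit_rates_ml(tr, sim$tip_states, "ER", k = 2)
  expect_equal(mine$model$rates[1], unname(fm$rates), tolerance = 1e-4)
  expect_equal(mine$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-6)
})
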