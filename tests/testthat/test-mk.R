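# Mk model likelihood, fitting, model weights, and marginal ASR.

test_that("two-tip two-state ER likelihood matches the closed form", {
  # tips joined at the root, both state 0, branch duration t each:
  # L = 1/2 [P00(t)^2 + P10(t)^2], P00(t) = (1 + exp(-2qt))/2
  q <- 0.3; t <- 1.7
  tr <- read_newick(sprintf("(A:%f,B:%f);", t, t), length_kind = "time")
  m <- mk_model(c("0", "1"), "ER", q, root_prior = "uniform")
  p00 <- (1 + exp(-2 * q * t)) / 2
  p10 <- (1 - exp(-2 * q * t)) / 2
  expect_equal(mk_loglik(tr, c(A = "0", B = "0"), m),
               log(0.5 * (p00^2 + p10^2)), tolerance = 1e-12)
})

test_that("vanishing rate drives the likelihood to the root prior", {
  tr <- rand_time_tree(6, seed = 1)
  x <- stats::setNames(rep("0", 6), tr$tip.label)
  m <- mk_model(c("0", "1"), "ER", 1e-12, root_prior = "uniform")
  expect_equal(mk_loglik(tr, x, m), log(0.5), tolerance = 1e-6)
})

test_that("likelihood equals exhaustive enumeration on small trees", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    tr <- rand_time_tree(n, seed = 100 + rep)
    k <- sample(2:3, 1)
    st <- letters[1:k]
    m <- mk_model(st, "ARD", stats::runif(k * (k - 1), 0.05, 0.6),
                  root_prior = "stationary")
    x <- stats::setNames(sample(st, n, replace = TRUE), tr$tip.label)
    expect_equal(mk_loglik(tr, x, m), enum_mk_loglik(tr, x, m),
                 tolerance = 1e-8)
  }
  # missing tips follow the ones-vector treatment
  tr <- rand_time_tree(5, seed = 7)
  m <- mk_model(c("0", "1"), "ER", 0.2)
  x <- stats::setNames(c("0", "?", "1", "0", "?"), tr$tip.label)
  expect_equal(mk_loglik(tr, x, m), enum_mk_loglik(tr, x, m),
               tolerance = 1e-8)
})

test_that("tip-state likelihoods sum to one over all assignments", {
  tr <- rand_time_tree(4, seed = 3)
  st <- c("0", "1")
  m <- mk_model(st, "ARD", c(0.3, 0.1), root_prior = "stationary")
  total <- 0
  for (code in 0:15) {
    bits <- as.integer(intToBits(code))[1:4]
    x <- stats::setNames(st[bits + 1L], tr$tip.label)
    total <- total + exp(mk_loglik(tr, x, m))
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("rate-matrix structures build correctly", {
  m <- mk_model(c("n", "p", "c"), "ORDERED", c(0.1, 0.2, 0.3, 0.4))
  expect_equal(m$Q["n", "c"], 0)         # non-adjacent forbidden
  expect_equal(m$Q["n", "p"], 0.1)
  expect_equal(m$Q["c", "p"], 0.4)
  expect_equal(unname(rowSums(m$Q)), rep(0, 3))
  mask <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  mc <- mk_model(c("0", "1"), "CUSTOM", 0.5, mask = t(mask))
  expect_equal(sum(mc$Q > 0), 1L)        # single allowed transition
  pi <- mk_stationary(mk_model(c("0", "1"), "ARD", c(0.2, 0.6))$Q)
  expect_equal(unname(pi), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("ML fitting respects model nesting and recovers rates", {
  tr <- sim_bd_tree(150, lambda = 0.08, mu = 0, seed = 5)
  m_true <- mk_model(c("0", "1"), "ER", 0.02)
  sim <- sim_traits(tr, m_true, root_state = "0", seed = 6)
  fe <- fit_mk(tr, sim$tip_states, "ER", seed = 1)
  fa <- fit_mk(tr, sim$tip_states, "ARD", seed = 1)
  expect_lte(fe$loglik, fa$loglik + 1e-6)          # nested models
  expect_gt(fe$model$rates, 0.02 / 3)
  expect_lt(fe$model$rates, 0.02 * 3)
  expect_false(fe$degenerate)
  # degenerate data flagged
  tr2 <- rand_time_tree(5, seed = 2)
  xs <- stats::setNames(rep("0", 5), tr2$tip.label)
  expect_warning(fd <- fit_mk(tr2, xs, "ER", states = c("0", "1")),
                 "identifiable")
  expect_true(fd$degenerate)
})

test_that("ER rate recovery succeeds in most replicates", {
  # data simulated under ER; fitted rate within a factor of 2 of truth in
  # >= 90% of replicates (scaled-down replicate count)
  ok <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    tr <- sim_bd_tree(200, lambda = 0.08, mu = 0, seed = 50 + r)
    m_true <- mk_model(c("0", "1"), "ER", 0.01)
    sim <- sim_traits(tr, m_true, root_state = "0", seed = 500 + r)
    if (length(unique(sim$tip_states)) < 2L) next
    f <- fit_mk(tr, sim$tip_states, "ER", n_starts = 2, seed = r)
    if (f$model$rates > 0.005 && f$model$rates < 0.02) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("Akaike weights follow the closed form and sum to one", {
  expect_equal(unname(akaike_weights(c(-10, -10), c(2, 2))), c(0.5, 0.5))
  # AICs 10 and 12 -> weights 1/(1+e^-1), e^-1/(1+e^-1)
  w <- akaike_weights(c(-(10 - 2 * 1) / 2, -(12 - 2 * 1) / 2), c(1, 1))
  expect_equal(unname(w), c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(unname(w), 3), c(0.731, 0.269))
  w3 <- akaike_weights(c(0, 0, -25), c(1, 1, 1))
  expect_lt(w3[3], 1e-10)                        # dominated by delta-AIC 50
  expect_equal(sum(w3), 1)
  # invariant under adding a constant to all log-likelihoods
  expect_equal(akaike_weights(c(-5, -9), c(1, 2)),
               akaike_weights(c(95, 91), c(1, 2)))
})

test_that("marginal ASR matches symmetry, limits and enumeration", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);", length_kind = "time")
  m <- mk_model(c("0", "1"), "ER", 0.3, root_prior = "uniform")
  asr <- marginal_asr(tr, c(A = "0", B = "0", C = "1", D = "1"), m)
  expect_equal(unname(asr$prob[5L, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(rowSums(asr$prob)), rep(1, 7), tolerance = 1e-9)

  # q -> 0 with uniform tip data: internal nodes converge to the tip state
  m0 <- mk_model(c("0", "1"), "ER", 1e-10, root_prior = "uniform")
  asr0 <- marginal_asr(tr, c(A = "0", B = "0", C = "0", D = "0"), m0)
  expect_true(all(asr0$prob[5:7, "0"] > 1 - 1e-6))

  # enumeration oracle at every internal node
  set.seed(21)
  for (rep in 1:4) {
    tr <- rand_time_tree(5, seed = 300 + rep)
    m <- mk_model(c("0", "1", "2"), "ER", stats::runif(1, 0.1, 0.5),
                  root_prior = "stationary")
    x <- stats::setNames(sample(c("0", "1", "2"), 5, TRUE), tr$tip.label)
    asr <- marginal_asr(tr, x, m)
    ref <- enum_marginal(tr, x, m)
    expect_equal(unname(asr$prob[6:9, ]), unname(ref), tolerance = 1e-8)
  }
})

test_that("the per-node ASR table anchors nodes by tip pairs", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);", length_kind = "time")
  m <- mk_model(c("0", "1"), "ER", 0.3, root_prior = "uniform")
  asr <- marginal_asr(tr, c(A = "0", B = "0", C = "1", D = "1"), m)
  tab <- asr_node_table(asr)
  expect_equal(nrow(tab), tr$Nnode)
  expect_equal(tab$p_0 + tab$p_1, rep(1, 3), tolerance = 1e-9)
  ab <- tab[tab$node == ape::getMRCA(tr, c("A", "B")), ]
  expect_setequal(c(ab$tip_a, ab$tip_b), c("A", "B"))
  expect_equal(ab$state, "0")
})

test_that("fitted ER rate agrees with an independent ML fit", {
  skip_if_not_installed("phytools")
  tr <- sim_bd_tree(80, lambda = 0.08, mu = 0, seed = 9)
  m_true <- mk_model(c("a", "b"), "ER", 0.03)
  sim <- sim_traits(tr, m_true, root_state = "a", seed = 10)
  ours <- fit_mk(tr, sim$tip_states, "ER", root_prior = "uniform", seed = 1)
  ref <- phytools::fitMk(tr, sim$tip_states, model = "ER",
                         pi = "equal")
  expect_equal(unname(ours$model$rates), unname(ref$rates),
               tolerance = 1e-3)
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
})
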