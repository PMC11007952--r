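# Synthetic-data generators: determinism and distributional properties.

test_that("every generator is deterministic under a fixed seed", {
  t1 <- sim_bd_tree(12, 0.05, 0.01, seed = 3)
  t2 <- sim_bd_tree(12, 0.05, 0.01, seed = 3)
  expect_identical(write_newick(t1), write_newick(t2))
  p <- default_rate_process("CIR")
  expect_identical(sim_rates(t1, p, seed = 4), sim_rates(t1, p, seed = 4))
  expect_identical(sim_branch_data(t1, sim_rates(t1, p, seed = 4),
                                   seed = 5)$counts,
                   sim_branch_data(t1, sim_rates(t1, p, seed = 4),
                                   seed = 5)$counts)
  m <- mk_model(c("0", "1"), "ER", 0.01)
  expect_identical(sim_traits(t1, m, "0", seed = 6)$tip_states,
                   sim_traits(t1, m, "0", seed = 6)$tip_states)
  expect_identical(sim_seq_pair(50, 90, seed = 7), sim_seq_pair(50, 90,
                                                                seed = 7))
  # the generators do not disturb the caller's RNG state
  set.seed(99); a <- stats::runif(1)
  set.seed(99); invisible(sim_bd_tree(5, 0.1, 0, seed = 1))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("birth-death trees have the requested size and valid ages", {
  for (s in 1:5) {
    tr <- sim_bd_tree(15, lambda = 0.06, mu = 0.02, seed = s)
    expect_equal(ape::Ntip(tr), 15L)
    expect_equal(tr$Nnode, 14L)            # n - 1 internal nodes
    ages <- node_ages(tr)
    expect_true(all(ages[tr$edge[, 1L]] > ages[tr$edge[, 2L]]))
  }
  tr2 <- sim_bd_tree(2, 0.1, 0, seed = 1)
  expect_equal(ape::Ntip(tr2), 2L)         # single split
})

test_that("pure-birth root ages match the closed-form expectation", {
  # forward simulation stopped one exponential wait after the n-th birth:
  # E[root age] = (1/lambda) * sum_{k=2}^{n} 1/k
  n <- 8; lam <- 0.2
  expected <- sum(1 / (2:n)) / lam
  roots <- vapply(1:1000, function(s)
    attr(sim_bd_tree(n, lam, 0, seed = s), "root_age"), 0)
  se <- stats::sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - expected), 3 * se)
})

test_that("rate simulation honours each process's law", {
  tr <- sim_bd_tree(20, 0.05, 0, seed = 8)
  # sigma2 -> 0 collapses all four models onto the base rate
  for (mdl in c("LN", "CIR", "UGAM", "WN")) {
    p <- rate_process(mdl, nu = 0.002, sigma2 = 1e-12,
                      theta = if (mdl == "CIR") 1 else NULL)
    r <- sim_rates(tr, p, seed = 9)
    expect_lt(max(abs(r - 0.002) / 0.002), 0.05)
  }
  # UGAM empirical moments match (nu, sigma2) at large branch count
  big <- sim_bd_tree(400, 0.08, 0, seed = 10)
  pu <- rate_process("UGAM", nu = 0.002, sigma2 = 1e-6)
  ru <- replicate(13, NULL)
  ru <- unlist(lapply(1:13, function(s) sim_rates(big, pu, seed = s)))
  n <- length(ru)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(ru) - 0.002), 3 * stats::sd(ru) / sqrt(n))
  expect_lt(abs(stats::var(ru) - 1e-6) / 1e-6, 0.1)
  # LN parent-child log-rate correlation is positive
  pl <- rate_process("LN", nu = 0.002, sigma2 = 0.02)
  rl <- sim_rates(big, pl, seed = 11)
  pe <- volvoclock:::.parent_edges(big)
  keep <- pe > 0L
  expect_gt(stats::cor(log(rl[keep]), log(rl[pe[keep]])), 0.2)
})

test_that("branch counts are Poisson with the stated mean", {
  tr <- sim_bd_tree(10, 0.05, 0, seed = 12)
  rates <- rep(0.001, nrow(tr$edge))
  bd <- sim_branch_data(tr, rates, sites = 1000, seed = 13)
  expect_true(all(bd$counts >= 0))
  expect_equal(attr(bd, "implied_lengths"), bd$counts / 1000)
  # unbiasedness of count/sites as a length estimator
  reps <- vapply(1:300, function(s)
    sim_branch_data(tr, rates, sites = 1000, seed = s)$counts[1L], 0L)
  mu <- 0.001 * tr$edge.length[1L] * 1000
  expect_lt(abs(mean(reps) - mu), 3 * stats::sd(reps) / sqrt(300))
  # zero-duration branch yields zero counts
  tr0 <- tr; tr0$edge.length[2L] <- 0
  expect_equal(sim_branch_data(tr0, rates, sites = 1000,
                               seed = 1)$counts[2L], 0L)
})

test_that("trait simulation returns consistent truth", {
  tr <- sim_bd_tree(15, 0.05, 0, seed = 14)
  m0 <- mk_model(c("0", "1"), "ER", 1e-12)
  s0 <- sim_traits(tr, m0, "0", seed = 15)
  expect_true(all(s0$tip_states == "0"))   # q = 0: everything root state
  expect_equal(s0$n_changes, 0L)
  # long-branch limit approaches the stationary distribution
  mlong <- mk_model(c("0", "1"), "ARD", c(0.3, 0.1))
  pi <- mk_stationary(mlong$Q)
  tips <- unlist(lapply(1:40, function(s) {
    trl <- tr; trl$edge.length <- trl$edge.length * 1000
    sim_traits(trl, mlong, "0", seed = s)$tip_states
  }))
  phat <- mean(tips == "0")
  n <- length(tips)
  expect_lt(abs(phat - pi[1L]), 4 * sqrt(pi[1L] * pi[2L] / n) + 0.02)
  # realized change count bounds the Fitch count of its own tips
  for (s in 1:10) {
    mm <- mk_model(c("0", "1"), "ER", 0.02)
    sim <- sim_traits(tr, mm, "0", seed = 100 + s)
    if (length(unique(sim$tip_states)) < 2L) next
    expect_gte(sim$n_changes,
               fitch_count(tr, sim$tip_states,
                           states = c("0", "1"))$count)
  }
})

test_that("simulated calibrations contain the truth and plant outliers", {
  tr <- sim_bd_tree(12, 0.05, 0, seed = 16)
  ages <- node_ages(tr)
  nodes <- c(13L, 14L, 15L)
  cal <- sim_calibrations(tr, ages, nodes, width = 10, seed = 17)
  expect_equal(nrow(cal), 3L)
  expect_true(all(cal$min_age <= cal$true_age &
                    cal$true_age <= cal$max_age))
  rc <- resolve_calibrations(tr, cal[, setdiff(names(cal), "node")])
  expect_equal(rc$node, nodes)             # tip pairs anchor the right nodes
  out <- sim_calibrations(tr, ages, nodes, width = 10,
                          outlier = list(node = 14L, offset = 300),
                          seed = 18)
  expect_gt(out$min_age[out$node == 14L], ages[14L] + 200)
  mo <- sim_calibrations(tr, ages, nodes, min_only = TRUE, seed = 19)
  expect_true(all(is.na(mo$max_age)))
  expect_true(all(mo$tail_low == 0.05))
})
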