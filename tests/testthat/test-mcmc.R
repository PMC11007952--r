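# Dating MCMC, posterior summaries, diagnostics, cross-validation.

make_strict_setup <- function(seed = 101, n_tips = 10) {
  tree <- sim_bd_tree(n_tips, lambda = 0.05, mu = 0, seed = seed)
  ages <- node_ages(tree)
  internal <- (n_tips + 1L):(n_tips + tree$Nnode)
  params <- rate_process("UGAM", nu = 0.002, sigma2 = 1e-10)
  rates <- sim_rates(tree, params, seed = seed + 1L)
  data <- sim_branch_data(tree, rates, sites = 5000, seed = seed + 2L)
  cal <- sim_calibrations(tree, ages, internal, width = 0.05,
                          seed = seed + 3L)
  list(tree = tree, ages = ages, data = data, cal = cal,
       internal = internal)
}

test_that("identical seeds give identical sample streams", {
  s <- make_strict_setup()
  dm <- dating_model(s$tree, s$cal, clock = "UGAM",
                     root_max = s$ages[11] * 3)
  a <- mcmc_date(dm, s$data, n_gen = 300, sample_every = 10, seed = 7,
                 n_chains = 2)
  b <- mcmc_date(dm, s$data, n_gen = 300, sample_every = 10, seed = 7,
                 n_chains = 2)
  expect_identical(a$chains[[1]]$ages, b$chains[[1]]$ages)
  expect_identical(a$chains[[2]]$rates, b$chains[[2]]$rates)
  c2 <- mcmc_date(dm, s$data, n_gen = 300, sample_every = 10, seed = 8,
                  n_chains = 1)
  expect_false(identical(a$chains[[1]]$ages, c2$chains[[1]]$ages))
})

test_that("near-strict-clock data with tight calibrations recover ages", {
  s <- make_strict_setup()
  dm <- dating_model(s$tree, s$cal, clock = "UGAM",
                     root_max = s$ages[11] * 3)
  ps <- mcmc_date(dm, s$data, n_gen = 3000, sample_every = 10, seed = 1,
                  n_chains = 1)
  post <- colMeans(volvoclock:::.stacked(ps, "ages"))
  truth <- s$ages[as.integer(names(post))]
  expect_lt(max(abs(post - truth) / truth), 0.01)
})

test_that("prior-only runs reproduce the soft-bound tail masses", {
  # two-sided calibrated node inside a 4-tip tree; likelihood switched off
  tree <- read_newick("((A:100,B:100):100,(C:120,D:120):80);",
                      length_kind = "time")
  cal <- data.frame(name = "c1", tip_a = "A", tip_b = "B",
                    min_age = 90, max_age = 110,
                    tail_low = 0.025, tail_high = 0.025)
  cal <- validate_calibrations(cal)
  dm <- dating_model(tree, cal, clock = "UGAM", root_max = 400)
  ps <- mcmc_date(dm, data = NULL, n_gen = 40000, sample_every = 10,
                  seed = 2, n_chains = 1)
  draws <- volvoclock:::.stacked(ps, "ages")
  calnode <- as.character(resolve_mrca(tree, "A", "B"))
  above <- mean(draws[, calnode] > 110)
  below <- mean(draws[, calnode] < 90)
  expect_lt(abs(above - 0.025), 0.005)
  expect_lt(abs(below - 0.025), 0.005)
})

test_that("prior-only node ages follow the conditioned birth-death law", {
  # uncalibrated node marginal compared against direct order-statistic
  # simulation via the quantile function, by a two-sample KS test
  tree <- read_newick("((((A:10,B:10):10,C:20):10,D:30):10,E:40);",
                      length_kind = "time")
  root_max <- 100
  dm <- dating_model(tree, NULL, clock = "UGAM", root_max = root_max)
  dm$hyper_means[c("lambda", "mu")] <- c(0.05, 0.02)
  ps <- mcmc_date(dm, NULL, n_gen = 120000, sample_every = 60, seed = 5,
                  n_chains = 1)
  ages <- volvoclock:::.stacked(ps, "ages")
  hyp <- volvoclock:::.stacked(ps, "hyper")
  # direct draws: for each retained sweep, an iid kernel draw below that
  # sweep's root age and birth/death rates, rejected against the ordering
  # constraint by resampling the same node (deepest non-root node: the
  # parent constraint is the root itself, child is age 10)
  node <- as.character(resolve_mrca(tree, "A", "D"))   # child of root
  lower <- 20   # its child (MRCA A,C) cannot go below its own children
  mcmc_draws <- ages[, node]
  direct <- vapply(seq_len(nrow(ages)), function(i) {
    repeat {
      u <- stats::runif(1)
      t <- bd_age_quantile(u, ages[i, 1L], hyp[i, "lambda"],
                           hyp[i, "mu"])
      if (t > ages[i, as.character(resolve_mrca(tree, "A", "C"))])
        return(t)
    }
  }, 0)
  ks <- suppressWarnings(stats::ks.test(mcmc_draws[seq(1, length(mcmc_draws),
                                                       by = 4)], direct))
  expect_gt(ks$p.value, 0.01)
})

test_that("convergence diagnostics separate good and broken chains", {
  m1 <- matrix(stats::rnorm(10000 * 2), 10000, 2,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(convergence_check(list(m1, m1))$table$rhat, c(1, 1),
               tolerance = 1e-3)
  set.seed(4)
  m2 <- matrix(stats::rnorm(10000 * 2), 10000, 2,
               dimnames = list(NULL, c("a", "b")))
  good <- convergence_check(list(m1, m2))
  expect_true(good$pass)
  expect_true(all(good$table$rhat < 1.01))
  m3 <- m2 + 10                                    # centred 10 SD apart
  expect_false(convergence_check(list(m1, m3))$pass)
  expect_error(convergence_check(list(m1, m2[, 1, drop = FALSE])),
               "unequal parameterization")
})

test_that("HPD intervals are shortest and match known distributions", {
  set.seed(6)
  u <- stats::runif(100000)
  hu <- hpd_interval(u, 0.95)
  expect_lt(abs(diff(hu) - 0.95), 0.02)
  z <- stats::rnorm(100000)
  hz <- hpd_interval(z, 0.95)
  expect_lt(abs(hz[1] + 1.96), 0.05)
  expect_lt(abs(hz[2] - 1.96), 0.05)
  expect_equal(hpd_interval(rep(3.5, 200)), c(3.5, 3.5))
  expect_error(hpd_interval(1:50), "at least")
  # shortest-window property against direct enumeration
  x <- sort(stats::rnorm(500))
  h <- hpd_interval(x, 0.9)
  m <- ceiling(0.9 * 500)
  widths <- x[m:500] - x[1:(500 - m + 1)]
  expect_equal(diff(h), min(widths))
})

test_that("chronogram summaries report mean, HPD and printed intervals", {
  s <- make_strict_setup()
  dm <- dating_model(s$tree, s$cal, clock = "UGAM",
                     root_max = s$ages[11] * 3)
  ps <- mcmc_date(dm, s$data, n_gen = 1500, sample_every = 10, seed = 3,
                  n_chains = 1)
  chron <- summarize_chronogram(ps)
  expect_true(all(chron$hpd_lower <= chron$mean_age + 1e-12))
  expect_true(all(chron$mean_age <= chron$hpd_upper + 1e-12))
  # printed older-bound-first
  expect_match(chron$hpd_printed[1],
               "^[0-9]+-[0-9]+$")
  ends <- as.numeric(strsplit(chron$hpd_printed[1], "-")[[1]])
  expect_gte(ends[1], ends[2])
  expect_equal(format_hpd(c(237, 349)), "349-237")
  # constant draws at one node collapse its summary to a point
  fake <- ps
  fake$chains[[1]]$ages[, 1L] <- 298           # the root column
  ch2 <- summarize_chronogram(fake)
  root_row <- ch2[ch2$node == as.integer(colnames(ps$chains[[1]]$ages))[1L], ]
  expect_equal(root_row$mean_age, 298)
  expect_equal(c(root_row$hpd_lower, root_row$hpd_upper), c(298, 298))
  txt <- attr(ch2, "tree_text")
  expect_match(txt, "age=298")
})

test_that("fossil cross-validation reports one row per fossil and flags a
           planted outlier", {
  tree <- sim_bd_tree(12, lambda = 0.05, mu = 0, seed = 31)
  ages <- node_ages(tree)
  internal <- 13:23
  params <- rate_process("UGAM", nu = 0.002, sigma2 = 4e-7)
  rates <- sim_rates(tree, params, seed = 32)
  data <- sim_branch_data(tree, rates, sites = 2000, seed = 33)
  # one fossil per node, as in a densely anchored cross-validation study,
  # with one calibration deliberately shifted off its true age
  out_node <- internal[order(-ages[internal])][5]
  cal <- sim_calibrations(tree, ages, internal, width = 2,
                          outlier = list(node = out_node, offset = 30),
                          seed = 34)
  dm <- dating_model(tree, cal, clock = "UGAM", root_max = ages[13] * 6)
  xv <- fossil_cross_validate(dm, data, n_gen = 2500, seed = 1)
  expect_equal(nrow(xv), nrow(cal))
  expect_equal(as.character(xv$calibration), cal$name)
  worst <- xv$calibration[which.max(abs(xv$deviation))]
  expect_equal(as.character(worst), cal$name[cal$node == out_node])
  expect_equal(attr(xv, "total_ss"), sum(xv$deviation^2))
  # the consistent fossils deviate far less than the planted one
  expect_gt(max(abs(xv$deviation)), 2 * stats::median(abs(xv$deviation)))
  cal1 <- cal[1, ]
  dm1 <- dating_model(tree, cal1, clock = "UGAM", root_max = 500)
  expect_error(fossil_cross_validate(dm1, data), "at least two")
})
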