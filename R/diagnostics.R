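# Posterior summaries: HPD intervals, convergence diagnostics, chronogram
# assembly, and leave-one-fossil-out cross-validation.

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing \code{ceiling(mass * n)} of the
#' sorted draws.
#'
#' @param x Numeric draws (>= 100 unless \code{min_draws} lowered).
#' @param mass Interval mass.
#' @param min_draws Minimum number of draws required.
#' @return Numeric \code{c(lower, upper)}.
#' @examples
#' hpd_interval(rnorm(10000))
#' @export
hpd_interval <- function(x, mass = 0.95, min_draws = 100L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < min_draws)
    stop("need at least ", min_draws, " draws for an HPD interval")
  xs <- sort(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1L], xs[n]))
  widths <- xs[m:n] - xs[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1L])
}

#' Format an HPD interval older-bound-first
#'
#' Chronogram intervals are conventionally printed with the older bound
#' first, e.g. \code{"349-237"}.
#' @param hpd Numeric \code{c(lower, upper)}.
#' @param digits Rounding.
#' @return Character scalar.
#' @export
format_hpd <- function(hpd, digits = 0) {
  paste0(round(hpd[2L], digits), "-", round(hpd[1L], digits))
}

#' Convergence diagnostics across chains
#'
#' Rank-normalized split-\eqn{\hat R} and effective sample size for every
#' node-age (and hyperparameter) column. Finite-sample noise can push the
#' raw \eqn{\hat R} estimate marginally below 1; it is floored at 1.
#'
#' @param samples A \code{posterior_samples} with >= 2 chains, or a list of
#'   equal-dimension draw matrices.
#' @param rhat_max,ess_min Pass thresholds.
#' @return List: \code{table} (parameter, rhat, ess), \code{pass}.
#' @export
convergence_check <- function(samples, rhat_max = 1.1, ess_min = 100) {
  mats <- if (inherits(samples, "posterior_samples")) {
    lapply(samples$chains, function(ch) {
      m <- cbind(ch$ages, ch$hyper[, c("nu", "sigma2")])
      drop_n <- floor(nrow(m) * samples$burn_in)
      m[(drop_n + 1L):nrow(m), , drop = FALSE]
    })
  } else samples
  if (length(mats) < 2L) stop("need at least two chains")
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[2L, ])) != 1L)
    stop("chains of unequal parameterization")
  n <- min(dims[1L, ])
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  p <- ncol(mats[[1L]])
  rhat <- ess <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(mats, function(m) m[, j], numeric(n))
    rhat[j] <- .split_rhat(draws)
    ess[j] <- sum(apply(draws, 2L, function(v)
      if (stats::var(v) == 0) length(v) else coda::effectiveSize(v)))
  }
  nm <- colnames(mats[[1L]])
  if (is.null(nm)) nm <- paste0("par", seq_len(p))
  tab <- data.frame(parameter = nm, rhat = rhat, ess = ess)
  list(table = tab, pass = all(rhat < rhat_max) && all(ess > ess_min))
}

# Rank-normalized split R-hat (chains split in half, ranks mapped through
# the normal quantile function), floored at 1.
.split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2L)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1L):n, , drop = FALSE])
  r <- matrix(rank(segs, ties.method = "average"), nrow(segs))
  z <- stats::qnorm((r - 0.375) / (length(segs) + 0.25))
  m <- ncol(z); nn <- nrow(z)
  means <- colMeans(z)
  if (stats::var(as.vector(z)) == 0) return(1)
  B <- nn * stats::var(means)
  W <- mean(apply(z, 2L, stats::var))
  if (W == 0) return(1)
  max(1, sqrt(((nn - 1) / nn * W + B / nn) / W))
}

#' Summarize posterior samples to a chronogram
#'
#' Per-node posterior mean age and 95\% HPD after burn-in, plus the
#' annotated NEXUS tree text.
#'
#' @param samples A \code{posterior_samples}.
#' @param mass HPD mass.
#' @param file Optional path for the annotated tree.
#' @return A \code{chronogram}: data.frame (node, mean_age, hpd_lower,
#'   hpd_upper, hpd_printed) with the annotated tree text as attribute
#'   \code{"tree_text"} and the posterior-mean tree as \code{"tree"}.
#' @export
summarize_chronogram <- function(samples, mass = 0.95, file = NULL) {
  ages <- .stacked(samples, "ages")
  nodes <- as.integer(colnames(ages))
  mean_age <- colMeans(ages)
  hpd <- t(apply(ages, 2L, hpd_interval, mass = mass,
                 min_draws = min(100L, nrow(ages))))
  tab <- data.frame(node = nodes, mean_age = mean_age,
                    hpd_lower = hpd[, 1L], hpd_upper = hpd[, 2L],
                    hpd_printed = apply(hpd, 1L, format_hpd),
                    row.names = NULL)
  ann <- lapply(seq_along(nodes), function(i)
    c(age = unname(mean_age[i]), hpd_lower = unname(hpd[i, 1L]),
      hpd_upper = unname(hpd[i, 2L])))
  names(ann) <- nodes
  mean_tree <- .tree_with_ages(samples$tree,
                               stats::setNames(mean_age, nodes))
  txt <- write_annotated_tree(mean_tree, ann, file = file)
  structure(tab, class = c("chronogram", "data.frame"),
            tree_text = if (is.null(file)) txt else NULL, tree = mean_tree)
}

#' Leave-one-out fossil cross-validation
#'
#' Each calibration is removed in turn and the dating re-run; the deviation
#' \eqn{D_i} is the posterior mean age of the calibrated node minus the
#' calibration midpoint (or minimum, for minimum-only rows).
#'
#' @param model A \code{dating_model} with >= 2 calibrations.
#' @param data A \code{branch_data} (or NULL).
#' @param n_gen,sample_every,seed,n_chains Passed to \code{mcmc_date}.
#' @return data.frame (calibration, node, reference_age, posterior_mean,
#'   deviation, sq_deviation) with total sum of squares as attribute
#'   \code{"total_ss"}.
#' @export
fossil_cross_validate <- function(model, data, n_gen = 4000L,
                                  sample_every = 10L, seed = 1L,
                                  n_chains = 1L) {
  cal <- model$calibrations
  if (is.null(cal) || nrow(cal) < 2L)
    stop("fossil cross-validation needs at least two calibrations")
  rows <- lapply(seq_len(nrow(cal)), function(i) {
    reduced <- cal[-i, , drop = FALSE]
    if (all(is.na(reduced$min_age)))
      stop("removing '", cal$name[i], "' leaves no minimum bound anywhere")
    m2 <- model; m2$calibrations <- reduced
    ps <- mcmc_date(m2, data, n_gen = n_gen, sample_every = sample_every,
                    seed = seed + i, n_chains = n_chains)
    ages <- .stacked(ps, "ages")
    pm <- mean(ages[, as.character(cal$node[i])])
    ref <- if (is.na(cal$max_age[i])) cal$min_age[i] else
      (cal$min_age[i] + cal$max_age[i]) / 2
    data.frame(calibration = cal$name[i], node = cal$node[i],
               reference_age = ref, posterior_mean = pm,
               deviation = pm - ref, sq_deviation = (pm - ref)^2)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_ss") <- sum(out$sq_deviation)
  out
}
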