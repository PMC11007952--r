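# Prior components for Bayesian node dating: soft-bound fossil calibration
# densities, the conditioned birth-death node-age prior, the four
# relaxed-clock rate processes, and the branch-length observation model.

## ---- soft-bound calibration densities --------------------------------------

#' Log density of a soft-bound fossil calibration
#'
#' Two-sided bound (min m, max M): mass \code{1 - tail_low - tail_high} is
#' uniform on [m, M]; the stated tail masses sit in exponential tails below m
#' and above M whose rates are chosen so the density is continuous at each
#' bound. Minimum-only bound: mass \code{1 - tail_low} in a diffuse
#' exponential component above m (scale \code{diffuse_scale}), \code{tail_low}
#' in a continuous exponential tail below m. Tail masses of zero recover hard
#' bounds (zero density outside). The density integrates to 1 over the real
#' line; for calibrations far from zero the mass below age 0 is negligible.
#'
#' @param age Age(s), My (vectorized).
#' @param cal One calibration row (list/data.frame row with \code{min_age},
#'   \code{max_age}, \code{tail_low}, \code{tail_high}).
#' @param diffuse_scale Scale (My) of the above-minimum component of a
#'   minimum-only calibration; defaults to the minimum age itself.
#' @return Log density values.
#' @examples
#' cal <- list(min_age = 1030, max_age = 1060, tail_low = 0.025,
#'             tail_high = 0.025)
#' exp(calibration_logdensity(1045, cal))
#' @export
calibration_logdensity <- function(age, cal, diffuse_scale = NULL) {
  m <- cal$min_age; M <- cal$max_age
  pL <- cal$tail_low; pU <- cal$tail_high
  out <- numeric(length(age))
  if (!is.na(m) && !is.na(M)) {
    h <- (1 - pL - pU) / (M - m)
    lo <- age < m; hi <- age > M
    out[!lo & !hi] <- log(h)
    out[lo] <- if (pL > 0) log(h) - (m - age[lo]) * h / pL else -Inf
    out[hi] <- if (pU > 0) log(h) - (age[hi] - M) * h / pU else -Inf
  } else if (!is.na(m)) {
    s <- if (is.null(diffuse_scale)) m else diffuse_scale
    h <- (1 - pL) / s
    lo <- age < m
    out[!lo] <- log(h) - (age[!lo] - m) / s
    out[lo] <- if (pL > 0) log(h) - (m - age[lo]) * h / pL else -Inf
  } else {
    # maximum-only: uniform on (0, M] with an upper tail
    h <- (1 - pU) / M
    hi <- age > M
    out[!hi] <- log(h)
    out[hi] <- if (pU > 0) log(h) - (age[hi] - M) * h / pU else -Inf
    out[age <= 0] <- -Inf
  }
  out
}

## ---- birth-death node-age prior --------------------------------------------

#' Conditional node-age density of the conditioned birth-death process
#'
#' Given the root age \eqn{t_1}, the non-root internal node ages of a
#' complete-sampling birth-death tree are i.i.d. (as order statistics) with
#' density proportional to
#' \eqn{\lambda r^2 e^{-r t} / (\lambda - \mu e^{-r t})^2} on \eqn{(0, t_1)},
#' \eqn{r = \lambda - \mu}. The critical case \eqn{\lambda = \mu} has the
#' closed form \eqn{(1 + \lambda t)^{-2}} up to normalization and is handled
#' analytically.
#'
#' @param t Node age(s) in My.
#' @param t_root Root age (conditioning value).
#' @param lambda,mu Birth and death rates (1/My), \code{lambda >= mu >= 0}.
#' @param log Return log density?
#' @return Density values (0 outside \code{(0, t_root)}).
#' @export
bd_age_density <- function(t, t_root, lambda, mu, log = FALSE) {
  stopifnot(lambda > 0, mu >= 0, t_root > 0)
  r <- lambda - mu
  dens <- numeric(length(t))
  inside <- t > 0 & t < t_root
  ti <- t[inside]
  if (abs(r) < 1e-12 * lambda) {        # critical case
    kern <- lambda / (1 + lambda * ti)^2
    norm <- lambda * t_root / (1 + lambda * t_root)
  } else {
    e <- exp(-r * ti)
    kern <- lambda * r^2 * e / (lambda - mu * e)^2
    norm <- lambda * (1 - exp(-r * t_root)) / (lambda - mu * exp(-r * t_root))
  }
  dens[inside] <- kern / norm
  if (log) log(dens) else dens
}

#' Quantile function of \code{bd_age_density} (inverse CDF)
#' @inheritParams bd_age_density
#' @param p Probabilities.
#' @return Ages.
#' @export
bd_age_quantile <- function(p, t_root, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-12 * lambda) {
    Fmax <- lambda * t_root / (1 + lambda * t_root)
    u <- p * Fmax
    return(u / (lambda * (1 - u)))
  }
  e1 <- exp(-r * t_root)
  Fmax <- lambda * (1 - e1) / (lambda - mu * e1)
  u <- p * Fmax
  y <- lambda * (1 - u) / (lambda - u * mu)   # y = exp(-r t)
  -log(y) / r
}

#' Log prior density of a full set of node ages
#'
#' Root age uniform on \code{(0, root_max]}; calibrated nodes follow their
#' soft-bound calibration density in place of the birth-death kernel; every
#' other internal node follows \code{\link{bd_age_density}} conditioned on
#' the root age. Parent ages must strictly exceed child ages.
#'
#' @param tree \code{phylo} (fixed rooted topology).
#' @param ages Numeric vector of length \code{Ntip + Nnode} (tips 0), ages in
#'   My by ape node id.
#' @param lambda,mu Birth-death rates.
#' @param root_max Hard maximum root age (My).
#' @param calibrations Optional calibration table with a \code{node} column
#'   (see \code{\link{resolve_calibrations}}).
#' @return Log density (\code{-Inf} for invalid configurations).
#' @export
bd_age_logprior <- function(tree, ages, lambda, mu, root_max,
                            calibrations = NULL) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  if (ages[root] > root_max || ages[root] <= 0) return(-Inf)
  dur <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  if (any(dur <= 0)) return(-Inf)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  cal_nodes <- integer(0)
  lp <- 0
  if (!is.null(calibrations) && nrow(calibrations)) {
    cal_nodes <- calibrations$node
    for (i in seq_len(nrow(calibrations)))
      lp <- lp + calibration_logdensity(ages[cal_nodes[i]], calibrations[i, ])
  }
  free <- setdiff(internal, c(root, cal_nodes))
  if (length(free))
    lp <- lp + sum(bd_age_density(ages[free], ages[root], lambda, mu,
                                  log = TRUE))
  if (!root %in% cal_nodes) lp <- lp - log(root_max)
  lp
}

## ---- relaxed-clock rate processes ------------------------------------------

#' Construct a relaxed-clock rate process
#'
#' @param model \code{"LN"} (autocorrelated lognormal: child log-rate normal
#'   around the parent log-rate with variance \code{sigma2 * dt}),
#'   \code{"CIR"} (Cox-Ingersoll-Ross mean-reverting diffusion with gamma
#'   stationary law), \code{"UGAM"} (i.i.d. gamma rates, mean \code{nu},
#'   variance \code{sigma2}), or \code{"WN"} (white noise: independent gamma
#'   rates whose variance \code{sigma2/dt} shrinks with branch duration).
#' @param nu Base rate (substitutions/site/My), > 0.
#' @param sigma2 Variance scale, > 0.
#' @param theta CIR reversion strength (1/My); the stationarity condition
#'   \code{2 * theta * nu / sigma2 > 1} is enforced.
#' @return A \code{rate_process} list.
#' @export
rate_process <- function(model = c("LN", "CIR", "UGAM", "WN"), nu,
                         sigma2, theta = NULL) {
  model <- match.arg(model)
  stopifnot(nu > 0, sigma2 > 0)
  if (model == "CIR") {
    if (is.null(theta)) stop("CIR needs a reversion parameter theta")
    stopifnot(theta > 0)
    if (2 * theta * nu / sigma2 <= 1)
      stop("CIR stationarity violated: need 2*theta*nu/sigma2 > 1 ",
           "(got ", format(2 * theta * nu / sigma2, digits = 4), ")")
  }
  structure(list(model = model, nu = nu, sigma2 = sigma2, theta = theta),
            class = "rate_process")
}

# CIR transition log density over time dt: r_t = Y / (2c) with
# Y ~ noncentral chi-square(df = 4 theta nu / sigma2, ncp = 2 c r_0 e^{-theta dt}),
# c = 2 theta / (sigma2 (1 - e^{-theta dt})). dchisq is log-stable where the
# Bessel-function form over/underflows.
.cir_translik <- function(r_to, r_from, dt, nu, sigma2, theta) {
  cc <- 2 * theta / (sigma2 * (1 - exp(-theta * dt)))
  df <- 4 * theta * nu / sigma2
  ncp <- 2 * cc * r_from * exp(-theta * dt)
  log(2 * cc) + stats::dchisq(2 * cc * r_to, df = df, ncp = ncp, log = TRUE)
}

#' Log prior density of per-branch rates under a clock process
#'
#' Branches are indexed by the rows of \code{tree$edge}. Autocorrelated
#' models (LN, CIR) condition each branch on its parent branch; the branches
#' stemming from the root are anchored at the base rate (LN) or the
#' stationary gamma law (CIR). Durations enter LN (variance scales with
#' \code{dt}), CIR (transition over \code{dt}) and WN (variance inversely
#' proportional to \code{dt}); UGAM ignores them, so its joint density
#' factorizes over branches.
#'
#' @param tree \code{phylo}.
#' @param rates Positive numeric vector, one per edge row.
#' @param durations Branch durations (My), one per edge row.
#' @param params A \code{rate_process}.
#' @return Log density.
#' @export
rate_prior_logdensity <- function(tree, rates, durations, params) {
  stopifnot(length(rates) == nrow(tree$edge),
            length(durations) == nrow(tree$edge))
  if (any(rates <= 0)) return(-Inf)
  nu <- params$nu; s2 <- params$sigma2
  switch(params$model,
    UGAM = sum(stats::dgamma(rates, shape = nu^2 / s2, rate = nu / s2,
                             log = TRUE)),
    WN = sum(stats::dgamma(rates, shape = nu^2 * durations / s2,
                           rate = nu * durations / s2, log = TRUE)),
    LN = {
      pe <- .parent_edges(tree)
      anchor <- ifelse(pe == 0L, nu, rates[pmax(pe, 1L)])
      sum(stats::dlnorm(rates, meanlog = log(anchor),
                        sdlog = sqrt(s2 * durations), log = TRUE))
    },
    CIR = {
      pe <- .parent_edges(tree)
      th <- params$theta
      shape <- 2 * th * nu / s2; rt <- 2 * th / s2
      rootward <- pe == 0L
      lp <- sum(stats::dgamma(rates[rootward], shape = shape, rate = rt,
                              log = TRUE))
      if (any(!rootward))
        lp <- lp + sum(.cir_translik(rates[!rootward], rates[pe[!rootward]],
                                     durations[!rootward], nu, s2, th))
      lp
    })
}

# For each edge row, the edge row of the parent branch (0 for root children).
.parent_edges <- function(tree) {
  edge_of_child <- integer(ape::Ntip(tree) + tree$Nnode)
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  edge_of_child[tree$edge[, 1L]]
}

## ---- branch-length observation model ---------------------------------------

#' Construct per-branch substitution data
#'
#' Poisson mode carries integer substitution counts and a site count
#' (synthetic data); normal mode carries observed branch lengths
#' (substitutions/site) with standard errors (real input trees). The default
#' SE for a length is \code{sqrt(length / sites)} floored at 1e-6.
#'
#' @param mode \code{"poisson"} or \code{"normal"}.
#' @param counts Integer substitution counts per edge row (poisson).
#' @param sites Number of sites (poisson; also used for default SEs).
#' @param lengths Observed branch lengths per edge row (normal).
#' @param se Standard errors (normal; default from \code{lengths, sites}).
#' @return A \code{branch_data} list.
#' @export
branch_data <- function(mode = c("poisson", "normal"), counts = NULL,
                        sites = NULL, lengths = NULL, se = NULL) {
  mode <- match.arg(mode)
  if (mode == "poisson") {
    stopifnot(!is.null(counts), !is.null(sites), sites >= 1,
              all(counts >= 0), all(counts == round(counts)))
    structure(list(mode = mode, counts = as.integer(counts),
                   sites = as.integer(sites)), class = "branch_data")
  } else {
    stopifnot(!is.null(lengths), all(lengths >= 0))
    if (is.null(se)) {
      if (is.null(sites)) stop("normal mode needs se or sites")
      se <- pmax(sqrt(lengths / sites), 1e-6)
    }
    se <- rep_len(se, length(lengths))
    structure(list(mode = mode, lengths = lengths, se = se),
              class = "branch_data")
  }
}

#' Branch-length observation log likelihood
#'
#' The expected substitution length of a branch is rate x duration. Poisson
#' mode: \code{count ~ Pois(rate * duration * sites)}; normal mode:
#' \code{length ~ N(rate * duration, se^2)}.
#'
#' @param rates,durations Per-edge-row rate (subst/site/My) and duration (My).
#' @param data A \code{branch_data}.
#' @return Log likelihood.
#' @export
branch_loglik <- function(rates, durations, data) {
  mu <- rates * durations
  if (data$mode == "poisson") {
    lam <- mu * data$sites
    if (any(lam == 0 & data$counts > 0)) return(-Inf)
    sum(stats::dpois(data$counts, pmax(lam, 1e-300), log = TRUE))
  } else {
    sum(stats::dnorm(data$lengths, mean = mu, sd = data$se, log = TRUE))
  }
}
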