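# Metropolis-within-Gibbs sampler for node ages, branch rates and
# hyperparameters on a fixed rooted topology.
#
# Updates are organised so that whole classes of parameters can be proposed
# simultaneously and accepted per-parameter: internal nodes (and branches)
# are two-coloured by depth parity, so no two simultaneously moved
# parameters are neighbours in the prior's dependency graph. Node-age
# proposals are uniform slides inside the (max child age, parent age)
# window, which is symmetric because the window does not depend on the
# node's own age. Branch rates are Gibbs-sampled where the gamma prior is
# conjugate to the Poisson observation model (UGAM, WN) and random-walk
# Metropolis on the log scale otherwise (LN, CIR). A whole-tree scale move
# (ages * c, rates / c) runs every 10th sweep to decorrelate the global
# time/rate confounding.

#' Assemble a dating model
#'
#' @param tree Rooted bifurcating \code{phylo}; branch lengths (if any) are
#'   ignored in favour of sampled node ages.
#' @param calibrations Optional \code{calibration_table}; resolved to nodes
#'   against \code{tree} if it lacks a \code{node} column.
#' @param clock Rate process family: \code{"LN"}, \code{"CIR"},
#'   \code{"UGAM"}, or \code{"WN"}.
#' @param root_max Hard maximum root age (My).
#' @param hyper_means Means of the vague exponential hyperpriors:
#'   \code{nu} (base rate), \code{sigma2}, \code{theta}, \code{lambda},
#'   \code{mu}.
#' @return A \code{dating_model} list.
#' @export
dating_model <- function(tree, calibrations = NULL, clock = c("CIR", "LN",
                         "UGAM", "WN"), root_max = 2000,
                         hyper_means = c(nu = 0.1, sigma2 = 1, theta = 1,
                                         lambda = 0.1, mu = 0.1)) {
  clock <- match.arg(clock)
  validate_tree(tree)
  if (!is.null(calibrations)) {
    if (is.null(calibrations$node))
      calibrations <- resolve_calibrations(tree, calibrations)
    oldest <- max(calibrations$min_age, na.rm = TRUE)
    if (is.finite(oldest) && root_max <= oldest)
      stop("root_max must exceed the oldest calibration minimum")
  }
  structure(list(tree = tree, calibrations = calibrations, clock = clock,
                 root_max = root_max, hyper_means = hyper_means),
            class = "dating_model")
}

# Precomputed index structure shared by all moves.
.mcmc_layout <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  ne <- nrow(edge)
  parent_edge <- .parent_edges(tree)              # 0 for root children
  child_edges <- split(seq_len(ne), edge[, 1L])   # edges below each node
  depth <- integer(nn)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(ne)))                     # preorder
    depth[ord$edge[e, 2L]] <- depth[ord$edge[e, 1L]] + 1L
  internal <- setdiff((ntip + 1L):nn, root)
  kid1 <- kid2 <- integer(nn)
  parent_node <- integer(nn)
  for (e in seq_len(ne)) {
    p <- edge[e, 1L]
    if (kid1[p] == 0L) kid1[p] <- edge[e, 2L] else kid2[p] <- edge[e, 2L]
    parent_node[edge[e, 2L]] <- p
  }
  list(ntip = ntip, nn = nn, root = root, edge = edge, ne = ne,
       parent_edge = parent_edge, child_edges = child_edges,
       kid1 = kid1, kid2 = kid2, parent_node = parent_node,
       depth = depth, internal = internal,
       class_even = internal[depth[internal] %% 2L == 0L],
       class_odd = internal[depth[internal] %% 2L == 1L],
       edge_even = which(depth[edge[, 2L]] %% 2L == 0L),
       edge_odd = which(depth[edge[, 2L]] %% 2L == 1L),
       postorder_edges = ord$edge)
}

# Calibration table flattened to plain vectors (+ precomputed density
# constants) for the sampler's hot loop.
.prep_cal <- function(cal, lay) {
  if (is.null(cal) || nrow(cal) == 0L)
    return(list(node = NULL, free = lay$internal, root_cal = FALSE))
  two <- !is.na(cal$min_age) & !is.na(cal$max_age)
  min_only <- !is.na(cal$min_age) & is.na(cal$max_age)
  h <- ifelse(two, (1 - cal$tail_low - cal$tail_high) /
                (cal$max_age - cal$min_age),
              ifelse(min_only, (1 - cal$tail_low) / cal$min_age,
                     (1 - cal$tail_high) / cal$max_age))
  list(node = cal$node, min = cal$min_age, max = cal$max_age,
       tl = cal$tail_low, th = cal$tail_high, two = two,
       min_only = min_only, h = h,
       s = ifelse(min_only, cal$min_age, NA),   # diffuse scale above min
       free = setdiff(lay$internal, cal$node),
       root_cal = lay$root %in% cal$node)
}

# Check-free birth-death kernel for the sampler's hot loop; the exported
# bd_age_density is the validated reference version.
.bd_kernel_log <- function(t, troot, lambda, mu) {
  r <- lambda - mu
  out <- rep(-Inf, length(t))
  inside <- t > 0 & t < troot
  ti <- t[inside]
  if (abs(r) < 1e-12 * lambda) {
    out[inside] <- log(lambda) - 2 * log1p(lambda * ti) -
      log(lambda * troot / (1 + lambda * troot))
  } else {
    e <- exp(-r * ti)
    e1 <- exp(-r * troot)
    out[inside] <- log(lambda) + 2 * log(r) - r * ti -
      2 * log(lambda - mu * e) -
      log(lambda * (1 - e1) / (lambda - mu * e1))
  }
  out
}

# Vectorized soft-bound log density at the calibrated nodes.
.cal_terms <- function(age, cv) {
  logh <- log(cv$h)
  # start from the in-bounds value, then overwrite tail regions
  out <- logh
  out[cv$min_only] <- logh[cv$min_only] -
    (age[cv$min_only] - cv$min[cv$min_only]) / cv$s[cv$min_only]
  lo <- !is.na(cv$min) & age < cv$min
  if (any(lo)) {
    out[lo] <- logh[lo] - (cv$min[lo] - age[lo]) * cv$h[lo] / cv$tl[lo]
    out[lo & cv$tl == 0] <- -Inf
  }
  hi <- !is.na(cv$max) & age > cv$max
  if (any(hi)) {
    out[hi] <- logh[hi] - (age[hi] - cv$max[hi]) * cv$h[hi] / cv$th[hi]
    out[hi & cv$th == 0] <- -Inf
  }
  out[age <= 0] <- -Inf
  out
}

# Per-edge rate-prior log terms; term e depends on rates[e], rates[pe(e)]
# and durations[e].
.rate_terms <- function(rates, durations, lay, clock, nu, s2, theta) {
  switch(clock,
    UGAM = stats::dgamma(rates, shape = nu^2 / s2, rate = nu / s2,
                         log = TRUE),
    WN = stats::dgamma(rates, shape = nu^2 * durations / s2,
                       rate = nu * durations / s2, log = TRUE),
    LN = {
      anchor <- rates[pmax(lay$parent_edge, 1L)]
      anchor[lay$parent_edge == 0L] <- nu
      stats::dlnorm(rates, meanlog = log(anchor),
                    sdlog = sqrt(s2 * durations), log = TRUE)
    },
    CIR = {
      out <- numeric(lay$ne)
      rw <- lay$parent_edge == 0L
      shape <- 2 * theta * nu / s2
      out[rw] <- stats::dgamma(rates[rw], shape = shape,
                               rate = 2 * theta / s2, log = TRUE)
      out[!rw] <- .cir_translik(rates[!rw], rates[lay$parent_edge[!rw]],
                                durations[!rw], nu, s2, theta)
      out
    })
}

# Subset evaluation of the per-edge rate-prior terms: durations_sub is
# aligned with idx; rates is the full vector (parents may lie outside idx).
.rate_terms_idx <- function(rates, durations_sub, lay, clock, nu, s2,
                            theta, idx) {
  r <- rates[idx]
  switch(clock,
    UGAM = stats::dgamma(r, shape = nu^2 / s2, rate = nu / s2, log = TRUE),
    WN = stats::dgamma(r, shape = nu^2 * durations_sub / s2,
                       rate = nu * durations_sub / s2, log = TRUE),
    LN = {
      pe <- lay$parent_edge[idx]
      anchor <- rates[pmax(pe, 1L)]
      anchor[pe == 0L] <- nu
      stats::dlnorm(r, meanlog = log(anchor),
                    sdlog = sqrt(s2 * durations_sub), log = TRUE)
    },
    CIR = {
      pe <- lay$parent_edge[idx]
      out <- numeric(length(idx))
      rw <- pe == 0L
      out[rw] <- stats::dgamma(r[rw], shape = 2 * theta * nu / s2,
                               rate = 2 * theta / s2, log = TRUE)
      out[!rw] <- .cir_translik(r[!rw], rates[pe[!rw]],
                                durations_sub[!rw], nu, s2, theta)
      out
    })
}

.lik_terms_idx <- function(rates_sub, durations_sub, data, idx) {
  if (is.null(data)) return(numeric(length(idx)))
  mu <- rates_sub * durations_sub
  if (data$mode == "poisson") {
    lam <- mu * data$sites
    lam[lam < 1e-300] <- 1e-300
    data$counts[idx] * log(lam) - lam - data$lgam[idx]
  } else {
    data$lognorm[idx] - (data$lengths[idx] - mu)^2 * data$inv2v[idx]
  }
}

# Per-edge observation log terms. Normalizing constants that do not depend
# on the parameters (lgamma(count + 1), the normal log-normalizer) are
# precomputed by .prep_data and reused every sweep.
.prep_data <- function(data) {
  if (is.null(data)) return(NULL)
  if (data$mode == "poisson") data$lgam <- lgamma(data$counts + 1)
  else {
    data$lognorm <- -log(data$se) - 0.5 * log(2 * pi)
    data$inv2v <- 1 / (2 * data$se^2)
  }
  data
}

.lik_terms <- function(rates, durations, data) {
  if (is.null(data)) return(numeric(length(rates)))
  mu <- rates * durations
  if (data$mode == "poisson") {
    lam <- mu * data$sites
    lam[lam < 1e-300] <- 1e-300
    data$counts * log(lam) - lam - data$lgam
  } else {
    data$lognorm - (data$lengths - mu)^2 * data$inv2v
  }
}

# Per-internal-node age-prior log terms (+ root uniform term on the root).
# calv is .prep_cal output augmented with $free (uncalibrated non-root
# internal nodes) and $root_cal.
.age_terms <- function(ages, lay, lambda, mu_bd, root_max, calv) {
  out <- numeric(lay$nn)
  troot <- ages[lay$root]
  if (troot <= 0 || troot > root_max) { out[lay$root] <- -Inf; return(out) }
  if (!is.null(calv$node))
    out[calv$node] <- .cal_terms(ages[calv$node], calv)
  if (length(calv$free))
    out[calv$free] <- .bd_kernel_log(ages[calv$free], troot, lambda, mu_bd)
  if (!isTRUE(calv$root_cal))
    out[lay$root] <- out[lay$root] - log(root_max)
  out
}

# h is ordered (nu, sigma2, theta, lambda, mu); means likewise.
.hyper_logprior <- function(h, means, clock) {
  if (h[[5L]] >= h[[4L]]) return(-Inf)          # supercritical prior only
  if (clock == "CIR" && 2 * h[[3L]] * h[[1L]] / h[[2L]] <= 1)
    return(-Inf)                                # CIR stationarity
  idx <- if (clock == "CIR") 1:5 else c(1L, 2L, 4L, 5L)
  sum(-log(means[idx]) - h[idx] / means[idx])   # exponential log densities
}

# Full joint log target; the per-move deltas below are consistent with this.
.log_target <- function(ages, rates, h, lay, model, data, calv) {
  dur <- ages[lay$edge[, 1L]] - ages[lay$edge[, 2L]]
  if (any(dur <= 0)) return(-Inf)
  hp <- .hyper_logprior(h, model$hyper_means, model$clock)
  if (!is.finite(hp)) return(-Inf)
  sum(.age_terms(ages, lay, h["lambda"], h["mu"], model$root_max, calv)) +
    sum(.rate_terms(rates, dur, lay, model$clock, h["nu"], h["sigma2"],
                    h["theta"])) +
    sum(.lik_terms(rates, dur, data)) + hp
}

.init_ages <- function(lay, cal, root_max) {
  ntip <- lay$ntip
  ages <- numeric(lay$nn)
  # per-node minimum from descendant calibration minima
  node_min <- numeric(lay$nn)
  if (!is.null(cal) && nrow(cal)) {
    mins <- ifelse(is.na(cal$min_age), 0, cal$min_age)
    node_min[cal$node] <- mins
  }
  for (e in seq_len(nrow(lay$postorder_edges))) {
    p <- lay$postorder_edges[e, 1L]; ch <- lay$postorder_edges[e, 2L]
    node_min[p] <- max(node_min[p], node_min[ch])
  }
  cal_max <- rep(Inf, lay$nn)
  if (!is.null(cal) && nrow(cal))
    cal_max[cal$node] <- ifelse(is.na(cal$max_age), Inf, cal$max_age)
  hi_root <- min(root_max, cal_max[lay$root])
  lo_root <- node_min[lay$root]
  if (lo_root >= hi_root) {
    # conflicting soft bounds: start above the descendant minima anyway
    # (finite prior density as long as the root hard maximum allows it)
    hi_root <- root_max
    if (lo_root >= hi_root)
      stop("calibration-infeasible root window (descendant minimum ",
           "exceeds the hard root maximum)")
  }
  ages[lay$root] <- lo_root + stats::runif(1, 0.55, 0.9) * (hi_root - lo_root)
  for (e in rev(seq_len(nrow(lay$postorder_edges)))) {   # preorder
    p <- lay$postorder_edges[e, 1L]; ch <- lay$postorder_edges[e, 2L]
    if (ch <= ntip) next
    hi <- min(ages[p], cal_max[ch])
    lo <- node_min[ch]
    if (lo >= hi) { lo <- 0; hi <- ages[p] }   # soft bounds absorb the miss
    ages[ch] <- lo + stats::runif(1, 0.55, 0.9) * (hi - lo)
  }
  ages
}

#' Sample node ages and branch rates by MCMC
#'
#' @param model A \code{dating_model}.
#' @param data A \code{branch_data}, or NULL for a prior-only run (the
#'   observation likelihood is switched off).
#' @param n_gen Number of sweeps per chain; one sweep updates every node
#'   age, every branch rate, and all hyperparameters.
#' @param sample_every Thinning interval.
#' @param seed Integer seed; chain c uses \code{seed + c - 1}.
#' @param n_chains Number of independent chains.
#' @param burn_in Fraction of each chain discarded by summaries (recorded
#'   here; draws are all returned).
#' @param init_retries Attempts at finding a finite-density starting state.
#' @return A \code{posterior_samples} object: per chain, matrices of node
#'   ages (columns = internal node ids), branch rates (columns = edge rows)
#'   and hyperparameters, with generation indices; plus layout metadata and
#'   acceptance rates.
#' @export
mcmc_date <- function(model, data = NULL, n_gen = 10000L,
                      sample_every = 10L, seed = 1L, n_chains = 2L,
                      burn_in = 0.2, init_retries = 200L) {
  stopifnot(inherits(model, "dating_model"))
  lay <- .mcmc_layout(model$tree)
  if (!is.null(data)) {
    nexp <- if (data$mode == "poisson") length(data$counts) else
      length(data$lengths)
    if (nexp != lay$ne) stop("data branches do not match topology")
  }
  calv <- .prep_cal(model$calibrations, lay)
  data <- .prep_data(data)
  chains <- lapply(seq_len(n_chains), function(ci)
    .with_seed(seed + ci - 1L,
               .run_chain(model, data, lay, calv, n_gen, sample_every,
                          init_retries, chain_id = ci)))
  structure(list(chains = chains, tree = model$tree, layout = lay,
                 model = model, burn_in = burn_in, seed = seed,
                 n_gen = n_gen, sample_every = sample_every),
            class = "posterior_samples")
}

.run_chain <- function(model, data, lay, calv, n_gen, sample_every,
                       init_retries, chain_id) {
  clock <- model$clock
  cal <- model$calibrations
  hm <- model$hyper_means

  # per-class precomputation: which edges touch a moved node, and who owns
  # each (exactly one endpoint of an edge can be in a parity class)
  cls_list <- list(lay$class_even, lay$class_odd)
  cls_pre <- lapply(cls_list, function(cls) {
    if (!length(cls)) return(NULL)
    in_cls <- logical(lay$nn); in_cls[cls] <- TRUE
    owner <- ifelse(in_cls[lay$edge[, 2L]], lay$edge[, 2L],
                    ifelse(in_cls[lay$edge[, 1L]], lay$edge[, 1L], 0L))
    own_edges <- which(owner > 0L)
    cal_rows <- which(calv$node %in% cls)
    list(cls = cls, own_edges = own_edges, owner = owner[own_edges],
         parent_of = lay$parent_node[cls],
         cal_rows = cal_rows,
         sub_calv = if (length(cal_rows))
           lapply(calv[c("node", "min", "max", "tl", "th", "two",
                         "min_only", "h", "s")],
                  function(v) v[cal_rows]),
         free_cls = intersect(cls, calv$free))
  })
  ecls_list <- list(lay$edge_even, lay$edge_odd)
  ecls_pre <- lapply(ecls_list, function(ecls) {
    if (!length(ecls)) return(NULL)
    own <- logical(lay$ne); own[ecls] <- TRUE
    pe <- lay$parent_edge
    dep <- which(pe > 0L & !own & own[pmax(pe, 1L)])  # terms moved via parent
    list(ecls = ecls, own = own, dep = dep, dep_pe = pe[dep])
  })

  # data-informed rate scale for initialization
  nu0 <- if (!is.null(data) && data$mode == "poisson")
    max(sum(data$counts) / data$sites, 1) else NULL

  for (try in seq_len(init_retries)) {
    ages <- tryCatch(.init_ages(lay, cal, model$root_max),
                     error = function(e) NULL)
    if (is.null(ages)) stop("calibration-infeasible starting ages")
    dur <- ages[lay$edge[, 1L]] - ages[lay$edge[, 2L]]
    nu <- if (is.null(nu0)) 0.01 else nu0 / sum(dur)
    h <- c(nu = nu, sigma2 = max(0.1 * nu, 1e-4), theta = 1,
           lambda = 2 / ages[lay$root], mu = 1 / ages[lay$root])
    if (clock %in% c("UGAM", "WN")) h["sigma2"] <- max(nu^2 / 4, 1e-8)
    rates <- rep(nu, lay$ne)
    lt <- .log_target(ages, rates, h, lay, model, data, calv)
    if (is.finite(lt)) break
    if (try == init_retries)
      stop("no valid initialization found after ", init_retries, " attempts")
  }

  n_keep <- floor(n_gen / sample_every)
  out_ages <- matrix(NA_real_, n_keep, length(lay$internal) + 1L)
  colnames(out_ages) <- c(lay$root, lay$internal)
  out_rates <- matrix(NA_real_, n_keep, lay$ne)
  hn <- c("nu", "sigma2", "theta", "lambda", "mu")
  out_h <- matrix(NA_real_, n_keep, length(hn), dimnames = list(NULL, hn))
  gen_idx <- integer(n_keep)
  acc <- c(age = 0, age_n = 0, rate = 0, rate_n = 0, hyper = 0, hyper_n = 0,
           scale = 0, scale_n = 0)
  kept <- 0L

  # cached per-edge terms
  dur <- ages[lay$edge[, 1L]] - ages[lay$edge[, 2L]]

  at_cur <- .age_terms(ages, lay, h["lambda"], h["mu"], model$root_max,
                       calv)
  rt_cur <- .rate_terms(rates, dur, lay, clock, h["nu"], h["sigma2"],
                        h["theta"])
  lk_cur <- .lik_terms(rates, dur, data)

  for (gen in seq_len(n_gen)) {
    ## -- node-age moves, two parity classes ---------------------------------
    for (pc in cls_pre) {
      if (is.null(pc)) next
      cls <- pc$cls
      lo <- pmax(ages[lay$kid1[cls]], ages[lay$kid2[cls]])
      hi <- ages[pc$parent_of]
      w <- hi - lo
      if (gen %% 2L == 0L) {
        prop <- lo + stats::runif(length(cls)) * w
      } else {
        # reflected normal step: symmetric, helps tightly calibrated nodes
        prop <- ages[cls] + stats::rnorm(length(cls), 0, 0.2 * w)
        over <- prop > hi; prop[over] <- 2 * hi[over] - prop[over]
        under <- prop < lo; prop[under] <- 2 * lo[under] - prop[under]
        bad <- prop < lo | prop > hi      # double reflection: just reject
        prop[bad] <- ages[cls][bad]
      }
      ages_new <- ages
      ages_new[cls] <- prop
      oe <- pc$own_edges
      dur_new_sub <- ages_new[lay$edge[oe, 1L]] - ages_new[lay$edge[oe, 2L]]
      # node-prior terms change only at the moved nodes
      at_new_cls <- numeric(lay$nn)
      if (length(pc$cal_rows)) {
        cn <- pc$sub_calv$node
        at_new_cls[cn] <- .cal_terms(ages_new[cn], pc$sub_calv)
      }
      if (length(pc$free_cls))
        at_new_cls[pc$free_cls] <- .bd_kernel_log(ages_new[pc$free_cls],
                                                  ages[lay$root],
                                                  h[["lambda"]], h[["mu"]])
      rt_new_sub <- .rate_terms_idx(rates, dur_new_sub, lay, clock,
                                    h[["nu"]], h[["sigma2"]], h[["theta"]],
                                    oe)
      lk_new_sub <- .lik_terms_idx(rates[oe], dur_new_sub, data, oe)
      d_edge <- (rt_new_sub - rt_cur[oe]) + (lk_new_sub - lk_cur[oe])
      dn <- numeric(lay$nn)
      dn[cls] <- at_new_cls[cls] - at_cur[cls]
      dsum <- rowsum(d_edge, pc$owner)
      ids <- as.integer(rownames(dsum))
      dn[ids] <- dn[ids] + dsum
      ok <- log(stats::runif(length(cls))) < dn[cls]
      ok[is.na(ok)] <- FALSE
      acc["age"] <- acc["age"] + sum(ok)
      acc["age_n"] <- acc["age_n"] + length(cls)
      if (any(ok)) {
        accepted <- cls[ok]
        ages[accepted] <- prop[ok]
        # patch caches: each edge/term is owned by at most one moved node,
        # so accepted nodes' own node terms and owned edge terms carry over
        # from the proposal evaluation
        at_cur[accepted] <- at_new_cls[accepted]
        sel <- pc$owner %in% accepted
        sub <- oe[sel]
        dur[sub] <- dur_new_sub[sel]
        rt_cur[sub] <- rt_new_sub[sel]
        lk_cur[sub] <- lk_new_sub[sel]
      }
    }

    ## -- root age slide ------------------------------------------------------
    {
      v <- lay$root
      lo <- max(ages[lay$kid1[v]], ages[lay$kid2[v]])
      hi <- model$root_max
      prop <- lo + stats::runif(1) * (hi - lo)
      ages_new <- ages; ages_new[v] <- prop
      re <- lay$child_edges[[as.character(v)]]   # only these durations move
      dur_new_sub <- prop - ages_new[lay$edge[re, 2L]]
      at_new <- .age_terms(ages_new, lay, h[["lambda"]], h[["mu"]],
                           model$root_max, calv)
      rt_new_sub <- .rate_terms_idx(rates, dur_new_sub, lay, clock,
                                    h[["nu"]], h[["sigma2"]], h[["theta"]],
                                    re)
      lk_new_sub <- .lik_terms_idx(rates[re], dur_new_sub, data, re)
      d <- sum(at_new) - sum(at_cur) + sum(rt_new_sub - rt_cur[re]) +
        sum(lk_new_sub - lk_cur[re])
      if (is.finite(d) && log(stats::runif(1)) < d) {
        ages <- ages_new
        dur[re] <- dur_new_sub
        at_cur <- at_new
        rt_cur[re] <- rt_new_sub
        lk_cur[re] <- lk_new_sub
      }
    }

    ## -- branch-rate updates -------------------------------------------------
    if (clock %in% c("UGAM", "WN") &&
        (is.null(data) || data$mode == "poisson")) {
      # conjugate gamma Gibbs (prior-only when data is NULL)
      if (clock == "UGAM") {
        sh0 <- h["nu"]^2 / h["sigma2"]; rt0 <- rep(h["nu"] / h["sigma2"],
                                                   lay$ne)
      } else {
        sh0 <- h["nu"]^2 * dur / h["sigma2"]; rt0 <- h["nu"] * dur /
          h["sigma2"]
      }
      cnt <- if (is.null(data)) 0 else data$counts
      expo <- if (is.null(data)) 0 else dur * data$sites
      rates <- stats::rgamma(lay$ne, shape = sh0 + cnt, rate = rt0 + expo)
      rates <- pmax(rates, 1e-12)
      rt_cur <- .rate_terms(rates, dur, lay, clock, h["nu"], h["sigma2"],
                            h["theta"])
      lk_cur <- .lik_terms(rates, dur, data)
      acc["rate"] <- acc["rate"] + lay$ne; acc["rate_n"] <- acc["rate_n"] +
        lay$ne
    } else {
      for (pe_cls in ecls_pre) {
        if (is.null(pe_cls)) next
        ecls <- pe_cls$ecls
        touched <- c(ecls, pe_cls$dep)   # own terms + child terms via parent
        prop <- rates
        step <- stats::rnorm(length(ecls), 0, 0.4)
        prop[ecls] <- rates[ecls] * exp(step)
        rt_new_sub <- .rate_terms_idx(prop, dur[touched], lay, clock,
                                      h[["nu"]], h[["sigma2"]],
                                      h[["theta"]], touched)
        lk_new_sub <- .lik_terms_idx(prop[ecls], dur[ecls], data, ecls)
        d_edge <- rt_new_sub - rt_cur[touched]
        de <- numeric(lay$ne)
        n1 <- length(ecls)
        de[ecls] <- d_edge[seq_len(n1)] + (lk_new_sub - lk_cur[ecls])
        if (length(pe_cls$dep)) {
          add <- rowsum(d_edge[-seq_len(n1)], pe_cls$dep_pe)
          ids <- as.integer(rownames(add))
          de[ids] <- de[ids] + add
        }
        ok <- log(stats::runif(length(ecls))) < de[ecls] + step
        ok[is.na(ok)] <- FALSE
        acc["rate"] <- acc["rate"] + sum(ok)
        acc["rate_n"] <- acc["rate_n"] + length(ecls)
        if (any(ok)) {
          A <- ecls[ok]
          rates[A] <- prop[A]
          rt_cur[A] <- rt_new_sub[seq_len(n1)][ok]
          lk_cur[A] <- lk_new_sub[ok]
          sel_dep <- pe_cls$dep_pe %in% A
          rt_cur[pe_cls$dep[sel_dep]] <- rt_new_sub[-seq_len(n1)][sel_dep]
        }
      }
    }

    ## -- hyperparameters -----------------------------------------------------
    hyps <- c("nu", "sigma2", if (clock == "CIR") "theta", "lambda", "mu")
    for (hp in hyps) {
      hnew <- h
      step <- stats::rnorm(1, 0, 0.5)
      hnew[hp] <- h[hp] * exp(step)
      d <- .hyper_logprior(hnew, hm, clock) - .hyper_logprior(h, hm, clock)
      at_new <- at_cur; rt_new <- rt_cur
      if (is.finite(d)) {
        if (hp %in% c("lambda", "mu")) {
          at_new <- .age_terms(ages, lay, hnew["lambda"], hnew["mu"],
                               model$root_max, calv)
          d <- d + sum(at_new) - sum(at_cur)
        } else {
          rt_new <- .rate_terms(rates, dur, lay, clock, hnew["nu"],
                                hnew["sigma2"], hnew["theta"])
          d <- d + sum(rt_new) - sum(rt_cur)
        }
      }
      ok <- is.finite(d) && log(stats::runif(1)) < d + step
      if (ok) { h <- hnew; at_cur <- at_new; rt_cur <- rt_new }
      acc["hyper"] <- acc["hyper"] + ok; acc["hyper_n"] <- acc["hyper_n"] + 1
    }

    ## -- whole-tree scale move (decorrelates global time/rate confounding).
    ## Expected branch lengths rate x duration are invariant, so the
    ## observation likelihood cancels exactly; only the priors move.
    {
      cfac <- exp(stats::rnorm(1, 0, 0.08))
      ages_new <- ages
      idx <- c(lay$root, lay$internal)
      ages_new[idx] <- ages[idx] * cfac
      rates_new <- rates / cfac
      dur_new <- dur * cfac
      at_new <- .age_terms(ages_new, lay, h[["lambda"]], h[["mu"]],
                           model$root_max, calv)
      rt_new <- .rate_terms(rates_new, dur_new, lay, clock, h[["nu"]],
                            h[["sigma2"]], h[["theta"]])
      jac <- (length(idx) - lay$ne) * log(cfac)
      d <- sum(at_new) - sum(at_cur) + sum(rt_new) - sum(rt_cur) + jac
      ok <- is.finite(d) && log(stats::runif(1)) < d
      if (ok) {
        ages <- ages_new; rates <- rates_new; dur <- dur_new
        at_cur <- at_new; rt_cur <- rt_new
        lk_cur <- .lik_terms(rates, dur, data)
      }
      acc["scale"] <- acc["scale"] + ok; acc["scale_n"] <- acc["scale_n"] + 1
    }

    if (gen %% 500L == 0L) {       # refresh caches (guards against drift)
      dur <- ages[lay$edge[, 1L]] - ages[lay$edge[, 2L]]
      at_cur <- .age_terms(ages, lay, h["lambda"], h["mu"], model$root_max,
                           calv)
      rt_cur <- .rate_terms(rates, dur, lay, clock, h["nu"], h["sigma2"],
                            h["theta"])
      lk_cur <- .lik_terms(rates, dur, data)
    }

    if (gen %% sample_every == 0L) {
      kept <- kept + 1L
      out_ages[kept, ] <- ages[c(lay$root, lay$internal)]
      out_rates[kept, ] <- rates
      out_h[kept, ] <- h[hn]
      gen_idx[kept] <- gen
    }
  }
  list(ages = out_ages[seq_len(kept), , drop = FALSE],
       rates = out_rates[seq_len(kept), , drop = FALSE],
       hyper = out_h[seq_len(kept), , drop = FALSE],
       generation = gen_idx[seq_len(kept)], chain = chain_id,
       acceptance = c(age = unname(acc["age"] / max(acc["age_n"], 1)),
                      rate = unname(acc["rate"] / max(acc["rate_n"], 1)),
                      hyper = unname(acc["hyper"] / max(acc["hyper_n"], 1)),
                      scale = unname(acc["scale"] / max(acc["scale_n"], 1))))
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", length(x$chains), "chain(s),",
      nrow(x$chains[[1]]$ages), "draws each (thin", x$sample_every,
      "), burn-in", x$burn_in, "\n")
  cat("  clock:", x$model$clock, "| acceptance (chain 1):",
      paste(names(x$chains[[1]]$acceptance),
            round(x$chains[[1]]$acceptance, 2), collapse = ", "), "\n")
  invisible(x)
}

# Post-burn-in draws of one quantity stacked across chains.
#' @keywords internal
.stacked <- function(samples, what = "ages") {
  do.call(rbind, lapply(samples$chains, function(ch) {
    m <- ch[[what]]
    drop_n <- floor(nrow(m) * samples$burn_in)
    m[(drop_n + 1L):nrow(m), , drop = FALSE]
  }))
}
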