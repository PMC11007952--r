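# Seeded generators with known ground truth: birth-death trees, clock-model
# rate histories, Poisson branch data, Mk trait histories, calibration
# tables, and sequence pairs. Every generator returns its truth next to the
# observable so recovery and coverage suites need no external data.
# Defaults are desk scale: 20 tips, 1000 sites, 3 calibrations.

#' Simulate a birth-death tree conditioned on its tip count
#'
#' Forward (Gillespie) simulation from two lineages until n extant lineages
#' are reached, with extinct lineages pruned; runs that die out are
#' restarted. Under pure birth the root age is a sum of exponentials with
#' mean \eqn{\lambda^{-1} \sum_{k=2}^{n-1} 1/k}.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param lambda,mu Birth and death rates (1/My), \code{lambda > mu >= 0}.
#' @param seed RNG seed.
#' @return Ultrametric \code{phylo} (\code{length_kind = "time"}) with tips
#'   at age 0; root age = attr \code{"root_age"}.
#' @export
sim_bd_tree <- function(n_tips, lambda = 0.05, mu = 0, seed = 1L) {
  stopifnot(n_tips >= 2L, lambda > mu, mu >= 0)
  .with_seed(seed, {
    repeat {
      res <- .sim_bd_forward(n_tips, lambda, mu)
      if (!is.null(res)) break
    }
    res
  })
}

.sim_bd_forward <- function(n_tips, lambda, mu) {
  # lineage bookkeeping by id; id 0 is the (unobserved) root lineage whose
  # first split at t = 0 creates ids 1 and 2
  nxt <- 3L
  alive <- c(1L, 2L)
  parent <- stats::setNames(c(0L, 0L), c("1", "2"))
  btime <- stats::setNames(c(0, 0), c("1", "2"))
  dtime <- numeric(0)
  t <- 0
  while (length(alive) < n_tips) {
    k <- length(alive)
    if (k == 0L) return(NULL)                  # extinct: retry
    t <- t + stats::rexp(1, k * (lambda + mu))
    who <- alive[sample.int(k, 1L)]
    if (stats::runif(1) < lambda / (lambda + mu)) {
      ids <- as.character(c(nxt, nxt + 1L))
      parent[ids] <- who
      btime[ids] <- t
      alive <- c(setdiff(alive, who), as.integer(ids))
      dtime[as.character(who)] <- t
      nxt <- nxt + 2L
    } else {
      alive <- setdiff(alive, who)
      dtime[as.character(who)] <- t
    }
  }
  # run on for one more exponential wait so the n-th split has positive
  # depth (stopping exactly at the n-th birth would put a node at age 0)
  stop_t <- t + stats::rexp(1, length(alive) * (lambda + mu))
  dtime[as.character(alive)] <- stop_t
  # build the pruned tree over extant tips by walking up from each tip
  anc_path <- function(id) {
    path <- integer(0)
    while (id != 0L) { path <- c(path, id); id <- parent[[as.character(id)]] }
    c(path, 0L)
  }
  paths <- lapply(alive, anc_path)
  # newick via recursive splitting on surviving children of each ancestor
  surv_children <- function(anc, tips) {
    # group tips by the child of 'anc' they descend through
    key <- vapply(tips, function(tp) {
      p <- paths[[match(tp, alive)]]
      p[which(p == anc) - 1L]
    }, 0L)
    split(tips, key)
  }
  node_time <- function(id) if (id == 0L) 0 else btime[[as.character(id)]]
  rec <- function(anc, tips) {
    if (length(tips) == 1L)
      return(list(txt = paste0("t", tips),
                  t = stop_t))
    groups <- surv_children(anc, tips)
    while (length(groups) == 1L) {           # ancestor with one surviving child
      anc <- as.integer(names(groups))
      groups <- surv_children(anc, tips)
    }
    subt <- lapply(names(groups), function(ch) {
      chi <- as.integer(ch)
      sub <- rec(chi, groups[[ch]])
      list(txt = paste0(sub$txt, ":", .fmt_num(sub$t - node_time(chi))),
           t = node_time(chi))
    })
    # this coalescent node sits at the birth time of the children group
    list(txt = paste0("(", paste(vapply(subt, `[[`, "", "txt"),
                                 collapse = ","), ")"),
         t = node_time(as.integer(names(groups)[1L])))
  }
  # start from the root (id 0) whose two children are ids 1 and 2
  top <- rec(0L, alive)
  tree <- ape::read.tree(text = paste0(top$txt, ";"))
  if (is.null(tree) || ape::Ntip(tree) != n_tips) return(NULL)
  attr(tree, "length_kind") <- "time"
  attr(tree, "root_age") <- stop_t - top$t
  tree
}

#' Default rate-process parameters for synthetic studies
#'
#' The recovery and coverage suites use one design rule for all four clock
#' models: the rate's coefficient of variation is \code{cv} on a reference
#' branch of \code{ref_duration} My (for UGAM and the CIR stationary law the
#' CV is duration-free). This makes the four processes comparably --
#' and moderately -- non-clock-like, rather than favouring any one model.
#'
#' @param model Clock model flag.
#' @param nu Base rate (substitutions/site/My).
#' @param cv Target coefficient of variation.
#' @param ref_duration Reference branch duration (My).
#' @param theta CIR reversion strength.
#' @return A \code{rate_process}.
#' @export
default_rate_process <- function(model, nu = 0.002, cv = 0.5,
                                 ref_duration = 15, theta = 1) {
  sigma2 <- switch(model,
    LN = log(1 + cv^2) / ref_duration,    # lognormal CV over ref_duration
    CIR = cv^2 * 2 * theta * nu,          # stationary gamma CV
    UGAM = (cv * nu)^2,
    WN = (cv * nu)^2 * ref_duration)
  rate_process(model, nu = nu, sigma2 = sigma2,
               theta = if (model == "CIR") theta else NULL)
}

#' Simulate per-branch rates under a clock process
#'
#' LN and CIR run sequentially down the tree (root branches anchored at the
#' base rate / stationary law); UGAM and WN draw branches independently.
#'
#' @param tree \code{phylo} with branch durations (My).
#' @param params A \code{rate_process}.
#' @param seed RNG seed.
#' @return Numeric rates, one per \code{tree$edge} row.
#' @export
sim_rates <- function(tree, params, seed = 1L) {
  ne <- nrow(tree$edge)
  dur <- tree$edge.length
  nu <- params$nu; s2 <- params$sigma2
  .with_seed(seed, switch(params$model,
    UGAM = stats::rgamma(ne, shape = nu^2 / s2, rate = nu / s2),
    WN = stats::rgamma(ne, shape = nu^2 * dur / s2, rate = nu * dur / s2),
    LN = {
      pe <- .parent_edges(tree)
      ord <- ape::reorder.phylo(tree, "postorder")
      rates <- numeric(ne)
      eidx <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
      for (e in rev(seq_len(ne))) {       # preorder
        i <- eidx[e]
        anchor <- if (pe[i] == 0L) nu else rates[pe[i]]
        rates[i] <- stats::rlnorm(1, log(anchor), sqrt(s2 * dur[i]))
      }
      rates
    },
    CIR = {
      pe <- .parent_edges(tree)
      th <- params$theta
      ord <- ape::reorder.phylo(tree, "postorder")
      rates <- numeric(ne)
      eidx <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                    paste(tree$edge[, 1L], tree$edge[, 2L]))
      for (e in rev(seq_len(ne))) {
        i <- eidx[e]
        if (pe[i] == 0L) {
          rates[i] <- stats::rgamma(1, shape = 2 * th * nu / s2,
                                    rate = 2 * th / s2)
        } else {
          cc <- 2 * th / (s2 * (1 - exp(-th * dur[i])))
          df <- 4 * th * nu / s2
          ncp <- 2 * cc * rates[pe[i]] * exp(-th * dur[i])
          rates[i] <- stats::rchisq(1, df = df, ncp = ncp) / (2 * cc)
        }
      }
      rates
    }))
}

#' Simulate Poisson branch substitution counts
#'
#' @param tree \code{phylo} with durations.
#' @param rates Per-edge-row rates (subst/site/My).
#' @param sites Number of sites.
#' @param seed RNG seed.
#' @return A \code{branch_data} (poisson mode) with implied lengths in
#'   attribute \code{"implied_lengths"} (= counts/sites).
#' @export
sim_branch_data <- function(tree, rates, sites = 1000L, seed = 1L) {
  stopifnot(sites >= 1L)
  lam <- rates * tree$edge.length * sites
  counts <- .with_seed(seed, stats::rpois(length(lam), lam))
  bd <- branch_data("poisson", counts = counts, sites = sites)
  attr(bd, "implied_lengths") <- counts / sites
  bd
}

#' Simulate a discrete character down a tree (Mk CTMC)
#'
#' Full-history simulation: the true state path is kept for every branch so
#' origin/loss counts of the realized history can be scored against
#' reconstructions.
#'
#' @param tree \code{phylo} with durations.
#' @param model An \code{mk_model}.
#' @param root_state Root state symbol.
#' @param seed RNG seed.
#' @return List: \code{tip_states} (named symbols), \code{node_states},
#'   \code{history} (per-edge-row segment matrices as in
#'   \code{stochastic_map}), \code{n_changes}.
#' @export
sim_traits <- function(tree, model, root_state, seed = 1L) {
  states <- model$states
  k <- length(states)
  r0 <- match(root_state, states)
  if (is.na(r0)) stop("root_state not in state space")
  Q <- model$Q
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  eidx <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))
  st <- integer(nn); st[ntip + 1L] <- r0
  history <- vector("list", nrow(tree$edge))
  n_changes <- 0L
  .with_seed(seed, {
    for (e in rev(seq_len(nrow(ord$edge)))) {     # preorder
      p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
      t_total <- ord$edge.length[e]
      s <- st[p]; t <- 0
      segs <- NULL
      repeat {
        rate <- -Q[s, s]
        wait <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (t + wait >= t_total) {
          segs <- rbind(segs, c(state = s, dwell = t_total - t))
          break
        }
        segs <- rbind(segs, c(state = s, dwell = wait))
        t <- t + wait
        pv <- Q[s, ]; pv[s] <- 0
        s <- sample.int(k, 1L, prob = pv / sum(pv))
        n_changes <- n_changes + 1L
      }
      history[[eidx[e]]] <- segs
      st[ch] <- s
    }
  })
  tips <- stats::setNames(states[st[seq_len(ntip)]], tree$tip.label)
  attr(tips, "states") <- states
  list(tip_states = tips, node_states = states[st], history = history,
       n_changes = n_changes)
}

#' Simulate a calibration table from true node ages
#'
#' Two-sided bounds that contain the truth by construction:
#' \code{min = truth - width * u1}, \code{max = truth + width * u2} with
#' u ~ U(0.2, 1). \code{min_only} rows drop the maximum. A planted outlier
#' (for cross-validation tests) shifts one calibration by \code{offset}.
#'
#' @param tree \code{phylo} (for tip pairs under each node).
#' @param ages Full node-age vector (tips 0).
#' @param nodes Internal node ids to calibrate.
#' @param width Bound half-width scale (My).
#' @param tails \code{c(tail_low, tail_high)}.
#' @param min_only Logical vector (recycled): drop the max bound?
#' @param outlier Optional \code{list(node =, offset =)} planting a
#'   conflicting calibration.
#' @param seed RNG seed.
#' @return A \code{calibration_table} with \code{node} column resolved.
#' @export
sim_calibrations <- function(tree, ages, nodes, width = 20, tails = c(0.025,
                             0.025), min_only = FALSE, outlier = NULL,
                             seed = 1L) {
  ntip <- ape::Ntip(tree)
  stopifnot(all(nodes > ntip))
  min_only <- rep_len(min_only, length(nodes))
  .with_seed(seed, {
    rows <- lapply(seq_along(nodes), function(i) {
      v <- nodes[i]
      truth <- ages[v]
      off <- if (!is.null(outlier) && outlier$node == v) outlier$offset else 0
      u <- stats::runif(2, 0.2, 1)
      mn <- max(truth + off - width * u[1L], 1e-3)
      mx <- truth + off + width * u[2L]
      # pick tips from the two child clades so the MRCA is exactly v
      kids <- tree$edge[tree$edge[, 1L] == v, 2L]
      ta <- .clade_tips(tree, kids[1L])[1L]
      tb <- .clade_tips(tree, kids[2L])[1L]
      data.frame(name = paste0("cal_", v), tip_a = tree$tip.label[ta],
                 tip_b = tree$tip.label[tb], min_age = mn,
                 max_age = if (min_only[i]) NA_real_ else mx,
                 tail_low = if (min_only[i]) 0.05 else tails[1L],
                 tail_high = if (min_only[i]) 0 else tails[2L],
                 node = v, true_age = truth)
    })
    validate_calibrations(do.call(rbind, rows))
  })
}

.clade_tips <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[1L]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == x, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Simulate a sequence pair with a target gap-free identity
#'
#' @param length Sequence length.
#' @param target_identity Percent in (0, 100].
#' @param seed RNG seed.
#' @param alphabet Residue alphabet.
#' @return Named character vector of two sequences whose positionwise
#'   identity equals the target to within 1/length resolution.
#' @export
sim_seq_pair <- function(length, target_identity = 95, seed = 1L,
                         alphabet = c("A", "C", "G", "T")) {
  stopifnot(target_identity > 0, target_identity <= 100, length >= 1L)
  .with_seed(seed, {
    a <- sample(alphabet, length, replace = TRUE)
    b <- a
    n_diff <- round(length * (1 - target_identity / 100))
    if (n_diff > 0) {
      pos <- sample.int(length, n_diff)
      for (p in pos)
        b[p] <- sample(setdiff(alphabet, a[p]), 1L)
    }
    c(seq_1 = paste(a, collapse = ""), seq_2 = paste(b, collapse = ""))
  })
}
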