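# Parsimony oracles: Fitch counting (unordered, equal costs), Sankoff
# dynamic programming with arbitrary (possibly infinite) cost matrices, and
# origin counting. These give the deterministic minimum-change counts that
# bound every stochastic-map history from below.

#' Fitch parsimony: minimum change count and per-node state sets
#'
#' Bottom-up Fitch pass for an unordered character under equal costs. Missing
#' tips (\code{"?"}) carry the full state set and never force a change.
#' Polytomies are handled by folding children in sequentially, which equals
#' resolving them arbitrarily (a message notes when this happens).
#'
#' @inheritParams mk_loglik
#' @param states Optional state space (defaults to observed symbols).
#' @return List: \code{count} (minimum number of changes),
#'   \code{state_sets} (per node, character vector of Fitch states),
#'   \code{states}.
#' @export
fitch_count <- function(tree, x, character = NULL, states = NULL) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  if (is.null(states)) states <- attr(x, "states")
  x <- x[tree$tip.label]
  obs <- x[!is.na(x) & x != MISSING_SYMBOL]
  if (!length(obs)) stop("all tips missing")
  if (is.null(states)) states <- sort(unique(obs))
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sets <- matrix(FALSE, nn, k)
  for (i in seq_len(ntip)) {
    if (is.na(x[i]) || x[i] == MISSING_SYMBOL) sets[i, ] <- TRUE
    else sets[i, match(x[i], states)] <- TRUE
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- ord$edge[, 1L]
  if (any(tabulate(parents) > 2L))
    message("polytomy present; Fitch pass folds children sequentially")
  count <- 0L
  done <- logical(nn)
  for (e in seq_len(nrow(ord$edge))) {
    p <- parents[e]
    if (done[p]) next
    done[p] <- TRUE
    kids <- ord$edge[parents == p, 2L]
    acc <- sets[kids[1L], ]
    for (ch in kids[-1L]) {
      inter <- acc & sets[ch, ]
      if (any(inter)) acc <- inter
      else { acc <- acc | sets[ch, ]; count <- count + 1L }
    }
    sets[p, ] <- acc
  }
  state_sets <- apply(sets, 1L, function(r) states[r], simplify = FALSE)
  list(count = count, state_sets = state_sets, states = states)
}

#' Sankoff parsimony with an arbitrary cost matrix
#'
#' Dynamic-programming minimum total cost over internal-node labelings.
#' Infinite costs encode forbidden transitions (e.g. irreversible loss-only
#' models). The backtrace reports one optimal labeling (ties broken
#' deterministically by state order) with its per-transition counts, and --
#' via a lexicographic second objective summed over the same edges -- the
#' minimum, across \emph{all} minimum-cost labelings, of the number of
#' transitions into a designated derived state set.
#'
#' @inheritParams fitch_count
#' @param cost k x k numeric cost matrix (rows = from, cols = to; zero
#'   diagonal; \code{Inf} = forbidden), dimnames = state symbols.
#' @param root_state Optional symbol forcing the root state.
#' @param derived Optional state symbol(s); transitions from outside into
#'   this set are "gains" for the secondary objective.
#' @return List: \code{cost}, \code{labeling} (state symbol per node),
#'   \code{transitions} (k x k count matrix for the reported labeling),
#'   \code{min_gains} (NA unless \code{derived} given).
#' @export
sankoff_cost <- function(tree, x, cost, root_state = NULL, derived = NULL,
                         character = NULL) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  states <- rownames(cost)
  stopifnot(!is.null(states), identical(states, colnames(cost)),
            all(diag(cost) == 0), all(cost >= 0))
  k <- length(states)
  x <- x[tree$tip.label]
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  gain <- if (is.null(derived)) matrix(0, k, k) else
    outer(!states %in% derived, states %in% derived, `&`) * 1
  BIG <- Inf

  # DP tables: S[v,s] = min subtree cost given state s at v; G[v,s] = min
  # gains among those min-cost subtree solutions (lexicographic objective;
  # valid because both objectives are edge sums and child subtrees are
  # independent given the child state).
  S <- matrix(BIG, nn, k)
  G <- matrix(BIG, nn, k)
  for (i in seq_len(ntip)) {
    if (is.na(x[i]) || x[i] == MISSING_SYMBOL) { S[i, ] <- 0; G[i, ] <- 0 }
    else {
      j <- match(x[i], states)
      if (is.na(j)) stop("state symbol '", x[i], "' not in cost matrix")
      S[i, j] <- 0; G[i, j] <- 0
    }
  }
  ord <- ape::reorder.phylo(tree, "postorder")
  parents <- ord$edge[, 1L]
  kidlist <- split(ord$edge[, 2L], parents)
  post_nodes <- unique(parents)
  # edge-choice tables for backtrace: best child state per (parent state,
  # child), lexicographic (cost, gains, state order)
  choice <- array(NA_integer_, c(nn, k))  # filled per child during backtrace
  edge_cost <- function(ch, s) {          # (cost, gain) of best child state
    cc <- cost[s, ] + S[ch, ]
    gg <- gain[s, ] + G[ch, ]
    ok <- is.finite(cc)
    if (!any(ok)) return(c(BIG, BIG, NA_integer_))
    best_c <- min(cc[ok])
    cand <- which(ok & cc <= best_c + 1e-9)
    best_g <- min(gg[cand])
    pick <- cand[gg[cand] <= best_g + 1e-9][1L]  # state-order tie-break
    c(best_c, best_g, pick)
  }
  for (p in post_nodes) {
    for (s in seq_len(k)) {
      tot_c <- 0; tot_g <- 0
      for (ch in kidlist[[as.character(p)]]) {
        ec <- edge_cost(ch, s)
        tot_c <- tot_c + ec[1L]; tot_g <- tot_g + ec[2L]
      }
      S[p, s] <- tot_c; G[p, s] <- tot_g
    }
  }
  root_allowed <- if (is.null(root_state)) rep(TRUE, k) else
    states == root_state
  if (!any(root_allowed & is.finite(S[root, ])))
    stop("no finite-cost labeling exists under this cost matrix")
  rc <- S[root, ]; rc[!root_allowed] <- BIG
  total <- min(rc)
  cand <- which(rc <= total + 1e-9)
  rg <- G[root, cand]
  min_gains <- if (is.null(derived)) NA_real_ else min(rg)
  root_pick <- cand[if (is.null(derived)) 1L else which(rg <= min(rg) + 1e-9)[1L]]

  # backtrace one optimal labeling (preorder)
  lab <- integer(nn)
  lab[root] <- root_pick
  pre <- rev(seq_len(nrow(ord$edge)))
  trans <- matrix(0L, k, k, dimnames = list(states, states))
  for (e in pre) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    pick <- edge_cost(ch, lab[p])[3L]
    lab[ch] <- pick
    if (pick != lab[p]) trans[lab[p], pick] <- trans[lab[p], pick] + 1L
  }
  list(cost = total, labeling = stats::setNames(states[lab], seq_len(nn)),
       transitions = trans, min_gains = min_gains, states = states)
}

#' Equal-cost matrix helper
#' @param states State symbols.
#' @return k x k matrix with 0 diagonal and 1 elsewhere.
#' @export
equal_costs <- function(states) {
  k <- length(states)
  m <- matrix(1, k, k, dimnames = list(states, states))
  diag(m) <- 0
  m
}

#' Count independent origins of a derived state
#'
#' Parsimony mode reports the minimum, over all minimum-change (equal-cost
#' Sankoff) reconstructions, of the number of transitions into the derived
#' state set. Simmap mode reports the modal count over sampled stochastic
#' maps (with the full distribution).
#'
#' @inheritParams fitch_count
#' @param derived Derived state symbol(s).
#' @param method \code{"parsimony-min-gains"} or \code{"simmap-modal"}.
#' @param model,n_maps,seed Simmap mode: the Mk model (fitted with
#'   \code{\link{fit_mk}} when NULL), number of maps, seed.
#' @return Parsimony mode: integer count. Simmap mode: list \code{count}
#'   (mode), \code{distribution}, \code{mean}.
#' @export
count_origins <- function(tree, x, derived,
                          method = c("parsimony-min-gains", "simmap-modal"),
                          character = NULL, states = NULL, model = NULL,
                          n_maps = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  if (is.null(states)) states <- attr(x, "states")
  obs <- x[!is.na(x) & x != MISSING_SYMBOL]
  if (is.null(states)) states <- sort(unique(obs))
  if (!any(obs %in% derived)) {
    warning("derived state absent from tips; zero origins")
    return(if (method == "parsimony-min-gains") 0L else
      list(count = 0L, distribution = table(0L), mean = 0))
  }
  if (method == "parsimony-min-gains") {
    sk <- sankoff_cost(tree, x, equal_costs(states), derived = derived)
    return(as.integer(round(sk$min_gains)))
  }
  if (is.null(model)) {
    fit <- fit_mk(tree, x, structure = "ER", states = states, seed = seed)
    model <- fit$model
  }
  maps <- stochastic_map(tree, x, model, n_maps = n_maps, seed = seed)
  tc <- count_transitions(maps, from = setdiff(states, derived), to = derived)
  list(count = tc$mode, distribution = tc$distribution, mean = tc$mean)
}
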