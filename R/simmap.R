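# Stochastic character mapping: sample full character histories (state
# changes with times on branches) from the posterior given tip data and an
# Mk model. Node states are drawn from the joint conditionals (pruning pass
# plus preorder sampling); branch paths conditioned on their endpoints are
# drawn by uniformization, which avoids the stalling of naive rejection
# sampling on long branches.

#' Sample stochastic character maps
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of histories to sample.
#' @param seed RNG seed (histories are reproducible under a fixed seed).
#' @param max_jumps Cap on candidate jumps per branch in the uniformization
#'   sampler; exceeding it raises an error naming the branch.
#' @return A \code{simmap_set}: list with \code{histories} (per map, a list
#'   indexed by child-node id of two-column matrices \code{state} /
#'   \code{dwell}, ordered rootward to tipward; dwell times sum to the branch
#'   duration), \code{node_states} (n_maps x nodes matrix of sampled state
#'   symbols), \code{tree}, \code{model}, \code{seed}.
#' @export
stochastic_map <- function(tree, x, model, n_maps = 100L, seed = 1L,
                           character = NULL, max_jumps = 1e6) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  stopifnot(n_maps >= 1L)
  pr <- .mk_prune(tree, x, model)
  if (pr$impossible) stop("tip data impossible under model")
  k <- length(model$states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  w <- .root_weights(model, pr$up[root, ])
  ord <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(ord$edge)))
  dur <- numeric(nn); dur[ord$edge[, 2L]] <- ord$edge.length

  Q <- model$Q
  omega <- max(-diag(Q)) * 1.05
  R <- if (omega > 0) diag(k) + Q / omega else diag(k)

  histories <- vector("list", n_maps)
  node_states <- matrix(NA_integer_, n_maps, nn)
  .with_seed(seed, {
    for (m in seq_len(n_maps)) {
      st <- integer(nn)
      pw <- w * pr$up[root, ]
      st[root] <- sample.int(k, 1L, prob = pw / sum(pw))
      for (e in pre_edges) {
        p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
        pv <- pr$P[[ch]][st[p], ] * pr$up[ch, ]
        st[ch] <- sample.int(k, 1L, prob = pv / sum(pv))
      }
      maps <- vector("list", nn)
      for (e in seq_len(nrow(ord$edge))) {
        ch <- ord$edge[e, 2L]
        maps[[ch]] <- .sample_path(st[ord$edge[e, 1L]], st[ch], dur[ch],
                                   Q, R, omega, pr$P[[ch]], max_jumps, ch)
      }
      histories[[m]] <- maps
      node_states[m, ] <- st
    }
  })
  state_syms <- matrix(model$states[node_states], n_maps, nn)
  structure(list(histories = histories, node_states = state_syms,
                 states = model$states, tree = tree, model = model,
                 seed = seed),
            class = "simmap_set")
}

# Endpoint-conditioned CTMC path on one branch by uniformization.
# Returns matrix with columns state (index), dwell.
.sample_path <- function(a, b, t, Q, R, omega, P, max_jumps, branch_id) {
  k <- nrow(Q)
  if (t <= 0 || omega == 0) {
    if (a != b && t <= 0)
      stop("state change required on zero-duration branch ", branch_id)
    return(cbind(state = a, dwell = t))
  }
  pab <- P[a, b]
  if (pab <= 0) stop("impossible endpoint pair on branch ", branch_id)
  # number of uniformized jumps: p(n) = dpois(n, omega t) R^n[a,b] / P[a,b]
  u <- stats::runif(1) * pab
  n <- 0L
  Rn <- diag(k)                 # R^n
  powers <- list(Rn)
  cum <- stats::dpois(0L, omega * t) * (a == b)
  while (cum < u) {
    n <- n + 1L
    if (n > max_jumps)
      stop("uniformization jump cap exceeded on branch ", branch_id)
    Rn <- Rn %*% R
    powers[[n + 1L]] <- Rn
    cum <- cum + stats::dpois(n, omega * t) * Rn[a, b]
  }
  if (n == 0L) return(cbind(state = a, dwell = t))
  # sample the chain states at the n jump epochs (s_0 = a fixed, s_n = b)
  s <- integer(n + 1L); s[1L] <- a; s[n + 1L] <- b
  if (n > 1L) for (j in 2L:n) {
    pv <- R[s[j - 1L], ] * powers[[n + 2L - j]][, b]
    s[j] <- sample.int(k, 1L, prob = pv / sum(pv))
  }
  times <- sort(stats::runif(n)) * t
  # merge virtual (self) jumps into dwell segments; epoch j holds state s[j]
  # from c(0, times)[j] until the next real jump
  keep <- c(TRUE, diff(s) != 0L)
  seg_states <- s[keep]
  seg_starts <- c(0, times)[keep]
  seg_ends <- c(seg_starts[-1L], t)
  cbind(state = seg_states, dwell = seg_ends - seg_starts)
}

#' Count state transitions across stochastic maps
#'
#' @param maps A \code{simmap_set}.
#' @param from,to Optional state symbols (or vectors of symbols) restricting
#'   the count to transitions from \code{from} into \code{to}; both NULL
#'   counts all changes.
#' @return List of class \code{transition_counts}: \code{counts} (per-history
#'   integer vector), \code{mean}, \code{mode}, \code{distribution} (table),
#'   and \code{matrix} (mean i -> j count matrix).
#' @export
count_transitions <- function(maps, from = NULL, to = NULL) {
  states <- maps$states
  k <- length(states)
  fi <- if (is.null(from)) seq_len(k) else match(from, states)
  ti <- if (is.null(to)) seq_len(k) else match(to, states)
  if (anyNA(fi) || anyNA(ti)) stop("state not in the model's state space")
  per <- integer(length(maps$histories))
  mat <- matrix(0, k, k, dimnames = list(states, states))
  for (m in seq_along(maps$histories)) {
    cnt <- 0L
    for (seg in maps$histories[[m]]) {
      if (is.null(seg) || nrow(seg) < 2L) next
      s <- seg[, "state"]
      fr <- s[-length(s)]; tt <- s[-1L]
      cnt <- cnt + sum(fr %in% fi & tt %in% ti)
      for (j in seq_along(fr)) mat[fr[j], tt[j]] <- mat[fr[j], tt[j]] + 1
    }
    per[m] <- cnt
  }
  tab <- table(per)
  mode <- as.integer(names(tab)[which.max(tab)])
  structure(list(counts = per, mean = mean(per), mode = mode,
                 distribution = tab, matrix = mat / length(per)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Transition counts over", length(x$counts), "histories: mode",
      x$mode, ", mean", format(x$mean, digits = 4), "\n")
  print(x$distribution)
  invisible(x)
}

#' Serialize stochastic maps in the simmap-annotated Newick dialect
#'
#' Branches are written as \code{:{state,time:state,time:...}} chains ordered
#' rootward to tipward.
#'
#' @param maps A \code{simmap_set}.
#' @param which Index of the history to serialize.
#' @return A Newick string.
#' @export
write_simmap <- function(maps, which = 1L) {
  tree <- maps$tree
  hist <- maps$histories[[which]]
  ntip <- ape::Ntip(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(v) {
    lab <- if (v <= ntip) tree$tip.label[v]
    else paste0("(", paste(vapply(children[[as.character(v)]], rec, ""),
                           collapse = ","), ")")
    if (v == ntip + 1L) return(lab)
    seg <- hist[[v]]
    chain <- paste(maps$states[seg[, "state"]],
                   .fmt_num(seg[, "dwell"]), sep = ",", collapse = ":")
    paste0(lab, ":{", chain, "}")
  }
  paste0(rec(ntip + 1L), ";")
}
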