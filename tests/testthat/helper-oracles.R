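# Independent oracles used across the suite: exhaustive enumeration for the
# Mk likelihood and parsimony, ancestor-set intersection for MRCAs, and
# recursive enumeration of all global alignments. These deliberately share
# no code with the implementations they check.

# random binary tree with uniform branch durations
rand_time_tree <- function(n, seed, min_len = 0.1, max_len = 2) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  attr(tr, "length_kind") <- "time"
  tr
}

# Exhaustive Mk likelihood: sum over every internal-node state assignment.
# Transition probabilities via expm (independent of the package's own
# exponential).
enum_mk_loglik <- function(tree, x, model) {
  st <- model$states
  k <- length(st)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    expm::expm(model$Q * tree$edge.length[e]))
  w <- switch(model$root_prior,
              stationary = mk_stationary(model$Q),
              uniform = rep(1 / k, k),
              stop("enum oracle supports stationary/uniform roots"))
  tip_allowed <- lapply(tree$tip.label, function(lab) {
    v <- x[[lab]]
    if (is.na(v) || v == "?") seq_len(k) else match(v, st)
  })
  total <- 0
  for (code in 0:(k^tree$Nnode - 1L)) {
    lab <- integer(nn)
    c2 <- code
    for (j in seq_len(tree$Nnode)) {
      lab[ntip + j] <- c2 %% k + 1L
      c2 <- c2 %/% k
    }
    # sum over tip ambiguity (missing tips)
    tipsets <- expand.grid(tip_allowed, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(tipsets))) {
      lab[seq_len(ntip)] <- as.integer(tipsets[r, ])
      pr <- w[lab[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][lab[tree$edge[e, 1L]], lab[tree$edge[e, 2L]]]
      total <- total + pr
    }
  }
  log(unname(total))
}

# Exhaustive marginal posterior at every internal node.
enum_marginal <- function(tree, x, model) {
  st <- model$states
  k <- length(st)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    expm::expm(model$Q * tree$edge.length[e]))
  w <- switch(model$root_prior, stationary = mk_stationary(model$Q),
              uniform = rep(1 / k, k))
  post <- matrix(0, nn, k)
  tipidx <- match(x[tree$tip.label], st)
  for (code in 0:(k^tree$Nnode - 1L)) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- tipidx
    c2 <- code
    for (j in seq_len(tree$Nnode)) {
      lab[ntip + j] <- c2 %% k + 1L
      c2 <- c2 %/% k
    }
    pr <- w[lab[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][lab[tree$edge[e, 1L]], lab[tree$edge[e, 2L]]]
    for (v in (ntip + 1L):nn) post[v, lab[v]] <- post[v, lab[v]] + pr
  }
  sweep(post[(ntip + 1L):nn, , drop = FALSE], 1L,
        rowSums(post[(ntip + 1L):nn, , drop = FALSE]), "/")
}

# MRCA by ancestor-set intersection: deepest node in both ancestor chains.
brute_mrca <- function(tree, a, b) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  chain <- function(v) {
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  ca <- chain(match(a, tree$tip.label))
  cb <- chain(match(b, tree$tip.label))
  common <- intersect(ca, cb)
  common[1L]   # chains are tip-to-root ordered; first shared is the MRCA
}

# All-alignments enumeration with affine gaps (tiny sequences only).
brute_align_score <- function(a, b, match_s = 5, mismatch = -4,
                              gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (toupper(av[i]) == toupper(bv[j])) match_s else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(av)) {
      pen <- gap_extend + if (last == "X") 0 else gap_open
      best <- max(best, -pen + rec(i + 1L, j, "X"))
    }
    if (j <= length(bv)) {
      pen <- gap_extend + if (last == "Y") 0 else gap_open
      best <- max(best, -pen + rec(i, j + 1L, "Y"))
    }
    best
  }
  rec(1L, 1L, "M")
}

# Exhaustive minimum-cost labeling (and minimum gains among optima).
brute_parsimony <- function(tree, x, states, cost = NULL, derived = NULL) {
  k <- length(states)
  if (is.null(cost)) cost <- equal_costs(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tipidx <- match(x[tree$tip.label], states)
  best_cost <- Inf
  best_gains <- Inf
  for (code in 0:(k^tree$Nnode - 1L)) {
    lab <- integer(nn)
    lab[seq_len(ntip)] <- tipidx
    c2 <- code
    for (j in seq_len(tree$Nnode)) {
      lab[ntip + j] <- c2 %% k + 1L
      c2 <- c2 %/% k
    }
    tc <- 0
    gains <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1L]]
      b <- lab[tree$edge[e, 2L]]
      tc <- tc + cost[a, b]
      if (!is.null(derived) && !states[a] %in% derived &&
          states[b] %in% derived)
        gains <- gains + 1L
    }
    if (tc < best_cost - 1e-9) { best_cost <- tc; best_gains <- gains }
    else if (tc < best_cost + 1e-9) best_gains <- min(best_gains, gains)
  }
  list(cost = best_cost, min_gains = best_gains)
}
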