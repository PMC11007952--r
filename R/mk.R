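# Mk (k-state continuous-time Markov) models for discrete characters on a
# fixed chronogram: likelihood by Felsenstein pruning, ML rate estimation,
# and marginal ancestral-state reconstruction.

#' Construct an Mk model
#'
#' @param states Ordered character vector of state symbols.
#' @param structure Rate-matrix structure: \code{"ER"} (one shared rate),
#'   \code{"ARD"} (one rate per ordered pair), \code{"ORDERED"} (transitions
#'   between adjacent states only, one rate per direction), or \code{"CUSTOM"}
#'   (explicit allowed-transition mask).
#' @param rates Numeric rate parameters (events per My), in the order defined
#'   by the structure: ER -- one rate; ARD -- row-major over ordered pairs
#'   i != j; ORDERED -- upward rates q(i,i+1) then downward q(i+1,i);
#'   CUSTOM -- row-major over \code{mask == TRUE} entries.
#' @param mask Logical k x k matrix of allowed transitions (CUSTOM only;
#'   diagonal ignored).
#' @param root_prior Root-state treatment: \code{"stationary"} (stationary
#'   distribution of the rate matrix; the default), \code{"uniform"}, or
#'   \code{"conditional"} (weights proportional to the root conditional
#'   likelihoods).
#' @return An object of class \code{mk_model}.
#' @examples
#' mk_model(c("0", "1"), "ER", rates = 0.01)
#' @export
mk_model <- function(states, structure = c("ER", "ARD", "ORDERED", "CUSTOM"),
                     rates, mask = NULL,
                     root_prior = c("stationary", "uniform", "conditional")) {
  structure <- match.arg(structure)
  root_prior <- match.arg(root_prior)
  k <- length(states)
  stopifnot(k >= 2L, !anyDuplicated(states))
  if (any(rates < 0)) stop("rates must be non-negative")
  np <- .mk_n_params(structure, k, mask)
  if (length(rates) == 1L && np > 1L) rates <- rep(rates, np)
  if (length(rates) != np)
    stop(structure, " with ", k, " states needs ", np, " rate(s)")
  if (structure == "CUSTOM") {
    stopifnot(is.matrix(mask), all(dim(mask) == k))
    diag(mask) <- FALSE
  }
  m <- structure(list(states = states, structure = structure, rates = rates,
                      mask = mask, root_prior = root_prior),
                 class = "mk_model")
  m$Q <- .mk_Q(m)
  m
}

.mk_n_params <- function(structure, k, mask = NULL) {
  switch(structure,
         ER = 1L, ARD = k * (k - 1L), ORDERED = 2L * (k - 1L),
         CUSTOM = { diag(mask) <- FALSE; sum(mask) })
}

# Rate matrix with rows summing to zero; disallowed transitions exactly 0.
.mk_Q <- function(m) {
  k <- length(m$states)
  Q <- matrix(0, k, k, dimnames = list(m$states, m$states))
  r <- m$rates
  switch(m$structure,
    ER = { Q[] <- r[1L]; diag(Q) <- 0 },
    ARD = {
      idx <- which(t(!diag(k)) == 1)          # row-major off-diagonals
      tQ <- t(Q); tQ[idx] <- r; Q <- t(tQ)
    },
    ORDERED = {
      for (i in seq_len(k - 1L)) {
        Q[i, i + 1L] <- r[i]                  # up
        Q[i + 1L, i] <- r[k - 1L + i]         # down
      }
    },
    CUSTOM = {
      tQ <- t(Q); tQ[t(m$mask)] <- r; Q <- t(tQ)
    })
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of an Mk rate matrix
#' @param Q Rate matrix (rows sum to 0).
#' @return Probability vector. Errors if the chain is reducible in a way that
#'   leaves the distribution undefined; callers needing a root prior on a
#'   reducible chain should use \code{"uniform"}.
#' @export
mk_stationary <- function(Q) {
  k <- nrow(Q)
  scale <- max(abs(Q))
  if (scale == 0) return(stats::setNames(rep(1 / k, k), rownames(Q)))
  A <- rbind(t(Q) / scale, rep(1, k))   # scaling keeps qr full-rank for
  pi <- tryCatch(qr.solve(A, c(rep(0, k), 1)),  # tiny rates
                 error = function(e) NULL)
  if (is.null(pi) || any(pi < -1e-8))
    stop("stationary distribution undefined (reducible rate matrix)")
  pi <- pmax(unname(pi), 0)
  stats::setNames(pi / sum(pi), rownames(Q))
}

# Transition-probability generator: returns function(t) -> P(t).
# Eigendecomposition once per Q; scaling-and-squaring (expm) fallback for
# defective/ill-conditioned matrices. Tolerance 1e-12 on row sums.
.mk_pfun <- function(Q) {
  k <- nrow(Q)
  eig <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eig <- !is.null(eig) &&
    (abs(rcond(eig$vectors)) > 1e-10)
  if (use_eig) {
    V <- eig$vectors; Vi <- solve(V); lam <- eig$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P / rowSums(P)
    }
  } else {
    function(t) {
      P <- .expm_ss(Q * t)
      P[P < 0] <- 0
      P / rowSums(P)
    }
  }
}

# Pade scaling-and-squaring matrix exponential (small dense matrices).
.expm_ss <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- A / 2^s
  X <- diag(n) + A + A %*% A / 2 + A %*% A %*% A / 6 +
    A %*% A %*% A %*% A / 24 + A %*% A %*% A %*% A %*% A / 120 +
    A %*% A %*% A %*% A %*% A %*% A / 720
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Tip likelihood matrix: ntip x k; "?" rows are all ones (standard missing-
# data treatment).
.tip_liks <- function(tree, x, states) {
  x <- x[tree$tip.label]
  bad <- !is.na(x) & x != MISSING_SYMBOL & !x %in% states
  if (any(bad))
    stop("state symbol '", x[bad][1L], "' outside the model's state space")
  L <- matrix(1, ape::Ntip(tree), length(states))
  obs <- !is.na(x) & x != MISSING_SYMBOL
  L[obs, ] <- 0
  L[cbind(which(obs), match(x[obs], states))] <- 1
  L
}

# Pruning pass. Returns list(up = (ntip+nnode) x k conditional likelihoods,
# scaled per node, logscale = accumulated log scalers, P = per-branch
# transition matrices indexed by child node).
.mk_prune <- function(tree, x, model) {
  k <- length(model$states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  if (!is.null(attr(tree, "length_kind")) &&
      attr(tree, "length_kind") != "time")
    warning("tree branch lengths are not durations (length_kind != 'time')")
  pfun <- .mk_pfun(model$Q)
  up <- matrix(0, nn, k)
  up[seq_len(ntip), ] <- .tip_liks(tree, x, model$states)
  P <- vector("list", nn)
  logscale <- 0
  # postorder: ape edges reordered
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    child <- ord$edge[e, 2L]
    P[[child]] <- pfun(ord$edge.length[e])
  }
  done <- logical(nn)
  parents <- ord$edge[, 1L]
  for (e in seq_len(nrow(ord$edge))) {
    p <- parents[e]
    if (done[p]) next
    done[p] <- TRUE
    kids <- ord$edge[parents == p, 2L]
    L <- rep(1, k)
    for (ch in kids) L <- L * as.vector(P[[ch]] %*% up[ch, ])
    sc <- max(L)
    if (sc <= 0) return(list(impossible = TRUE))
    up[p, ] <- L / sc
    logscale <- logscale + log(sc)
  }
  list(up = up, logscale = logscale, P = P, impossible = FALSE)
}

.root_weights <- function(model, root_lik) {
  switch(model$root_prior,
         stationary = mk_stationary(model$Q),
         uniform = rep(1 / length(model$states), length(model$states)),
         conditional = {
           if (sum(root_lik) <= 0) rep(1 / length(root_lik), length(root_lik))
           else root_lik / sum(root_lik)
         })
}

#' Mk log-likelihood of one discrete character
#'
#' Felsenstein pruning over the tree; per-branch transition probabilities by
#' matrix exponential of the model's rate matrix; the root state is
#' integrated out under the model's root prior. Missing tips (\code{"?"})
#' contribute a vector of ones.
#'
#' @param tree \code{phylo} with branch lengths in My (durations).
#' @param x Named character vector of tip states (\code{"?"} = missing), or a
#'   \code{trait_matrix} plus \code{character}.
#' @param model An \code{mk_model}.
#' @param character Character name, when \code{x} is a \code{trait_matrix}.
#' @return Log-likelihood (scalar; \code{-Inf} for impossible data).
#' @export
mk_loglik <- function(tree, x, model, character = NULL) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  pr <- .mk_prune(tree, x, model)
  if (pr$impossible) return(-Inf)
  root <- ape::Ntip(tree) + 1L
  w <- .root_weights(model, pr$up[root, ])
  val <- sum(w * pr$up[root, ])
  if (val <= 0) return(-Inf)
  log(val) + pr$logscale
}

#' Fit an Mk model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) on log-rates with seeded multi-start;
#' rates are constrained to [1e-9, 1e3] events/My.
#'
#' @inheritParams mk_loglik
#' @param structure Rate-matrix structure (see \code{\link{mk_model}}).
#' @param root_prior Root-state treatment.
#' @param n_starts Number of random restarts.
#' @param seed RNG seed for the restarts.
#' @param mask CUSTOM-structure transition mask.
#' @return List: \code{model} (fitted \code{mk_model}), \code{loglik},
#'   \code{n_params}, \code{convergence} (per-start optim codes),
#'   \code{degenerate} (TRUE when all observed tips share one state, leaving
#'   the likelihood flat as the rate tends to 0).
#' @export
fit_mk <- function(tree, x, structure = "ER", root_prior = "stationary",
                   n_starts = 5L, seed = 1L, character = NULL, mask = NULL,
                   states = NULL) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  if (is.null(states)) states <- attr(x, "states")
  obs <- x[!is.na(x) & x != MISSING_SYMBOL]
  if (is.null(states)) states <- sort(unique(obs))
  degenerate <- length(unique(obs)) < 2L
  if (degenerate)
    warning("all observed tips share one state; rate is not identifiable")
  np <- .mk_n_params(structure, length(states), mask)
  lb <- log(1e-9); ub <- log(1e3)
  # crude rate scale: one change per total tree length
  scale0 <- 1 / max(sum(tree$edge.length), 1e-9)
  nll <- function(logr) {
    m <- mk_model(states, structure, exp(logr), mask = mask,
                  root_prior = root_prior)
    -mk_loglik(tree, x, m)
  }
  best <- NULL; codes <- integer(0)
  starts <- .with_seed(seed,
    c(list(rep(log(scale0), np)),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i)
        log(scale0) + stats::rnorm(np, 0, 2))))
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s0, lb), ub), nll, method = "L-BFGS-B",
                   lower = lb, upper = ub),
      error = function(e) NULL)
    if (is.null(fit)) next
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  model <- mk_model(states, structure, exp(best$par), mask = mask,
                    root_prior = root_prior)
  list(model = model, loglik = -best$value, n_params = np,
       convergence = codes, degenerate = degenerate)
}

#' Akaike weights for a set of fitted models
#'
#' \eqn{AIC_m = 2k_m - 2\log L_m}; weights are
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_m = AIC_m - \min AIC}. All fits must be on identical data.
#'
#' @param loglik Numeric vector of maximum log-likelihoods.
#' @param n_params Integer vector of parameter counts.
#' @return Numeric vector of weights summing to 1, names preserved.
#' @examples
#' akaike_weights(c(ER = -10, ARD = -8), c(1, 2))
#' @export
akaike_weights <- function(loglik, n_params) {
  stopifnot(length(loglik) == length(n_params), length(loglik) >= 2L)
  aic <- 2 * n_params - 2 * loglik
  d <- aic - min(aic)
  w <- exp(-d / 2)
  stats::setNames(w / sum(w), names(loglik))
}

#' Marginal ancestral-state reconstruction
#'
#' Per-node marginal posterior state probabilities by an up--down
#' (outside-likelihood) pass, consistent with \code{mk_loglik}'s root
#' treatment.
#'
#' @inheritParams mk_loglik
#' @return List of class \code{asr_result}: \code{prob} ((ntip+nnode) x k
#'   matrix of state probabilities; tip rows are their observed states or the
#'   posterior for missing tips), \code{loglik}, \code{model}.
#' @export
marginal_asr <- function(tree, x, model, character = NULL) {
  if (inherits(x, "trait_matrix")) x <- .trait_column(x, character, tree)
  pr <- .mk_prune(tree, x, model)
  if (pr$impossible) stop("data impossible under model")
  k <- length(model$states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  w <- .root_weights(model, pr$up[root, ])

  down <- matrix(0, nn, k)
  down[root, ] <- w
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))  # preorder over edges
  parents <- ord$edge[, 1L]
  kidlist <- split(ord$edge[, 2L], parents)
  for (e in pre) {
    p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    sibs <- setdiff(kidlist[[as.character(p)]], ch)
    msg <- down[p, ]
    for (s in sibs) msg <- msg * as.vector(pr$P[[s]] %*% pr$up[s, ])
    v <- as.vector(msg %*% pr$P[[ch]])
    sc <- max(v)
    down[ch, ] <- if (sc > 0) v / sc else v
  }
  prob <- pr$up * down
  prob <- prob / pmax(rowSums(prob), .Machine$double.xmin)
  colnames(prob) <- model$states
  ll <- log(sum(w * pr$up[root, ])) + pr$logscale
  structure(list(prob = prob, loglik = ll, model = model, tree = tree),
            class = "asr_result")
}

#' Tabulate a marginal reconstruction per internal node
#'
#' Each internal node is identified both by its ape id and by a
#' representative tip pair whose MRCA it is (one tip from each child
#' clade), which survives node renumbering across tools.
#'
#' @param asr An \code{asr_result} from \code{\link{marginal_asr}}.
#' @return data.frame: node, tip_a, tip_b, state (highest-probability
#'   state), probability, plus one \code{p_<state>} column per state.
#' @export
asr_node_table <- function(asr) {
  tree <- asr$tree
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  rows <- lapply(internal, function(v) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    ta <- .clade_tips(tree, kids[1L])[1L]
    tb <- .clade_tips(tree, kids[2L])[1L]
    p <- asr$prob[v, ]
    best <- which.max(p)
    out <- data.frame(node = v, tip_a = tree$tip.label[ta],
                      tip_b = tree$tip.label[tb],
                      state = asr$model$states[best],
                      probability = unname(p[best]))
    for (s in asr$model$states) out[[paste0("p_", s)]] <- unname(p[s])
    out
  })
  do.call(rbind, rows)
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Marginal ancestral-state reconstruction\n")
  cat("  states:", paste(x$model$states, collapse = ", "),
      "| logLik:", format(x$loglik, digits = 6), "\n")
  root <- ape::Ntip(x$tree) + 1L
  cat("  root: ",
      paste(sprintf("P(%s)=%.3f", x$model$states, x$prob[root, ]),
            collapse = "  "), "\n")
  invisible(x)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's random state
# afterwards. Every stochastic entry point in the package routes through
# this, so identical seeds give identical streams without side effects.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  eval.parent(substitute(expr))
}
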