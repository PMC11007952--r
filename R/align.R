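# Needleman-Wunsch global alignment with affine gap penalties (Gotoh), and
# percent identity under the two common column conventions. Used for the
# cryptic-species screen (e.g. ITS-2 pairs from co-typic strains).

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Default scoring follows common nucleotide practice: match +5,
#' mismatch -4, gap open 10, gap extend 0.5 (penalties positive). A
#' substitution matrix (dimnames = alphabet) replaces match/mismatch for
#' protein input. Backtrace ties break deterministically: diagonal
#' (match/mismatch) over gap-in-B over gap-in-A.
#'
#' @param seq_a,seq_b Non-empty sequences (character scalars).
#' @param match,mismatch Scores used when \code{sub_matrix} is NULL.
#' @param gap_open,gap_extend Positive penalties; opening a gap of length L
#'   costs \code{gap_open + L * gap_extend}.
#' @param sub_matrix Optional substitution score matrix.
#' @return A \code{pairwise_alignment}: \code{aligned_a}, \code{aligned_b}
#'   (equal length, gap symbol \code{"-"}), \code{score}, \code{scheme}.
#' @examples
#' aln <- global_align("ACGT", "AGT")
#' percent_identity(aln)
#' @export
global_align <- function(seq_a, seq_b, match = 5, mismatch = -4,
                         gap_open = 10, gap_extend = 0.5,
                         sub_matrix = NULL) {
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  score_of <- if (is.null(sub_matrix)) {
    function(x, y) ifelse(toupper(x) == toupper(y), match, mismatch)
  } else {
    alpha <- rownames(sub_matrix)
    function(x, y) {
      i <- match(toupper(x), alpha); j <- match(toupper(y), alpha)
      if (is.na(i) || is.na(j))
        stop("residue outside the substitution table alphabet")
      sub_matrix[i, j]
    }
  }
  NEG <- -1e18
  # M: a[i] aligned to b[j]; X: gap in B (a[i] over '-'); Y: gap in A
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  X[-1L, 1L] <- -gap_open - gap_extend * seq_len(n)
  Y[1L, -1L] <- -gap_open - gap_extend * seq_len(m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- score_of(a[i], b[j])
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                               Y[i, j + 1L] - gap_open - gap_extend,
                               X[i, j + 1L] - gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                               X[i + 1L, j] - gap_open - gap_extend,
                               Y[i + 1L, j] - gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # backtrace with deterministic tie preference M > X > Y
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1L, m + 1L],
                                        X[n + 1L, m + 1L],
                                        Y[n + 1L, m + 1L]))]
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      s <- score_of(a[i], b[j])
      target <- M[i + 1L, j + 1L] - s
      state <- if (abs(M[i, j] - target) < tol) "M"
               else if (abs(X[i, j] - target) < tol) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      out_a <- c(a[i], out_a); out_b <- c("-", out_b)
      v <- X[i + 1L, j + 1L]
      state <- if (abs(M[i, j + 1L] - gap_open - gap_extend - v) < tol) "M"
               else if (abs(X[i, j + 1L] - gap_extend - v) < tol) "X"
               else "Y"
      i <- i - 1L
    } else {
      out_a <- c("-", out_a); out_b <- c(b[j], out_b)
      v <- Y[i + 1L, j + 1L]
      state <- if (abs(M[i + 1L, j] - gap_open - gap_extend - v) < tol) "M"
               else if (abs(X[i + 1L, j] - gap_open - gap_extend - v) < tol)
                 "X"
               else "Y"
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = score,
                 scheme = list(match = match, mismatch = mismatch,
                               gap_open = gap_open, gap_extend = gap_extend,
                               sub_matrix = !is.null(sub_matrix))),
            class = "pairwise_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' \code{"all-columns"}: identical columns over the full alignment length.
#' \code{"ungapped-columns"}: identical columns over columns with no gap
#' (the convention used for identity within conserved regions).
#'
#' @param aln A \code{pairwise_alignment}.
#' @param convention Column convention.
#' @return Percentage in [0, 100].
#' @export
percent_identity <- function(aln, convention = c("all-columns",
                                                 "ungapped-columns")) {
  convention <- match.arg(convention)
  a <- strsplit(aln$aligned_a, "")[[1L]]
  b <- strsplit(aln$aligned_b, "")[[1L]]
  if (!length(a)) stop("zero-length alignment")
  idn <- toupper(a) == toupper(b) & a != "-"
  denom <- if (convention == "all-columns") length(a) else
    sum(a != "-" & b != "-")
  if (denom == 0L) stop("no ungapped columns")
  100 * sum(idn) / denom
}

#' Pairwise identity report for a sequence set
#'
#' Aligns every pair (or a given list of pairs) and tabulates percent
#' identity -- the cryptic-species screen.
#'
#' @param seqs Named character vector (e.g. from \code{read_fasta}).
#' @param pairs Optional 2-column matrix/data.frame of sequence names.
#' @param convention Identity convention.
#' @param ... Passed to \code{global_align}.
#' @return data.frame: seq_a, seq_b, aligned_length, identities,
#'   percent_identity, convention.
#' @export
identity_report <- function(seqs, pairs = NULL,
                            convention = "all-columns", ...) {
  if (is.null(pairs)) {
    nm <- names(seqs)
    pairs <- t(utils::combn(nm, 2L))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    aln <- global_align(seqs[[pairs[r, 1L]]], seqs[[pairs[r, 2L]]], ...)
    aa <- strsplit(aln$aligned_a, "")[[1L]]
    bb <- strsplit(aln$aligned_b, "")[[1L]]
    data.frame(seq_a = pairs[r, 1L], seq_b = pairs[r, 2L],
               aligned_length = length(aa),
               identities = sum(toupper(aa) == toupper(bb) & aa != "-"),
               percent_identity = percent_identity(aln, convention),
               convention = convention)
  })
  do.call(rbind, rows)
}
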