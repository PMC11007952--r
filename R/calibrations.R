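# Fossil calibration tables. A calibration names a node (MRCA of two tips)
# and constrains its age with a minimum and/or maximum bound (My); the bound
# is "soft": a stated tail mass sits outside it (see calibration_density).

#' Parse a printed fossil age specification
#'
#' Conventions, as printed in fossil calibration tables:
#' \itemize{
#'   \item \code{"1047 +13/-17"}: point age with asymmetric uncertainty ->
#'     min 1030, max 1060.
#'   \item \code{"609 +/-5"}: symmetric -> min 604, max 614.
#'   \item \code{"MIN: 350"}: minimum-only bound.
#'   \item \code{"1056-948"}: range printed older bound first -> min 948,
#'     max 1056.
#' }
#'
#' @param spec Character scalar.
#' @return List with \code{min_age} and \code{max_age} (either may be NA, not
#'   both).
#' @export
parse_age_spec <- function(spec) {
  s <- trimws(spec)
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  out <- if (grepl("^MIN:", s, ignore.case = TRUE)) {
    list(min_age = as.numeric(sub("(?i)^MIN:\\s*", "", s, perl = TRUE)),
         max_age = NA_real_)
  } else if (grepl(paste0("^", num, "\\s*\\+", num, "/-", num, "$"), s)) {
    p <- as.numeric(regmatches(s, gregexpr(num, s))[[1]])
    list(min_age = p[1] - p[3], max_age = p[1] + p[2])
  } else if (grepl(paste0("^", num, "\\s*\\+/-\\s*", num, "$"), s)) {
    p <- as.numeric(regmatches(s, gregexpr(num, s))[[1]])
    list(min_age = p[1] - p[2], max_age = p[1] + p[2])
  } else if (grepl(paste0("^", num, "\\s*-\\s*", num, "$"), s)) {
    p <- as.numeric(regmatches(s, gregexpr(num, s))[[1]])
    list(min_age = min(p), max_age = max(p))  # printed older-first
  } else {
    stop("malformed age spec: '", spec, "'")
  }
  if (!is.na(out$min_age) && !is.na(out$max_age) &&
      out$min_age >= out$max_age)
    stop("age spec '", spec, "' yields min >= max")
  out
}

#' Read a fossil calibration table
#'
#' Expected TSV columns: \code{name}, \code{tip_a}, \code{tip_b},
#' \code{age_spec}, and optionally \code{tail_low}, \code{tail_high} (tail
#' masses outside the bounds; defaults 0.05 below a pure minimum, 0.025 per
#' side of a two-sided bound).
#'
#' @param file TSV path.
#' @return A \code{calibration_table} data.frame with columns \code{name},
#'   \code{tip_a}, \code{tip_b}, \code{min_age}, \code{max_age},
#'   \code{tail_low}, \code{tail_high}.
#' @export
read_calibrations <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "#")
  need <- c("name", "tip_a", "tip_b", "age_spec")
  if (!all(need %in% names(df)))
    stop("calibration TSV needs columns: ", paste(need, collapse = ", "))
  parsed <- lapply(df$age_spec, parse_age_spec)
  out <- data.frame(
    name = df$name, tip_a = df$tip_a, tip_b = df$tip_b,
    min_age = vapply(parsed, `[[`, 0, "min_age"),
    max_age = vapply(parsed, `[[`, 0, "max_age"),
    stringsAsFactors = FALSE)
  two_sided <- !is.na(out$min_age) & !is.na(out$max_age)
  out$tail_low <- if ("tail_low" %in% names(df)) df$tail_low else
    ifelse(two_sided, 0.025, 0.05)
  out$tail_high <- if ("tail_high" %in% names(df)) df$tail_high else
    ifelse(two_sided, 0.025, 0)
  validate_calibrations(out)
}

#' Validate a calibration table
#' @param cal Data frame as produced by \code{read_calibrations}.
#' @return The table, classed \code{calibration_table}; errors on violation.
#' @export
validate_calibrations <- function(cal) {
  with(cal, {
    if (any(is.na(min_age) & is.na(max_age)))
      stop("calibration with neither min nor max age")
    both <- !is.na(min_age) & !is.na(max_age)
    if (any(both & min_age >= max_age)) stop("calibration min >= max")
    if (any(tail_low < 0 | tail_low >= 0.5 | tail_high < 0 | tail_high >= 0.5))
      stop("tail masses must lie in [0, 0.5)")
  })
  class(cal) <- c("calibration_table", "data.frame")
  cal
}

#' Write a calibration table in the input TSV dialect
#' @param cal A \code{calibration_table}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_calibrations <- function(cal, file) {
  spec <- ifelse(is.na(cal$max_age), paste0("MIN: ", cal$min_age),
                 paste0(cal$max_age, "-", cal$min_age))
  df <- data.frame(name = cal$name, tip_a = cal$tip_a, tip_b = cal$tip_b,
                   age_spec = spec, tail_low = cal$tail_low,
                   tail_high = cal$tail_high)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Attach calibrations to tree nodes
#'
#' @param tree A \code{phylo}.
#' @param cal A \code{calibration_table}.
#' @return The table with an extra integer \code{node} column (ape node ids).
#' @export
resolve_calibrations <- function(tree, cal) {
  cal$node <- mapply(function(a, b) resolve_mrca(tree, a, b),
                     cal$tip_a, cal$tip_b)
  if (anyDuplicated(cal$node))
    stop("two calibrations resolve to the same node (",
         cal$name[duplicated(cal$node)][1L], ")")
  cal
}
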