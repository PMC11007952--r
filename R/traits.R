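# Discrete trait matrices: taxa x characters, with named state spaces and
# "?" as the missing-data symbol.

MISSING_SYMBOL <- "?"

#' Construct a trait matrix
#'
#' @param data data.frame of character state symbols (character columns),
#'   row names = taxon names.
#' @param state_spaces Optional named list: for each character, the vector of
#'   admissible state symbols (excluding \code{"?"}). Inferred from the
#'   observed symbols when omitted; \code{"?"} cells are excluded from
#'   inference.
#' @return A \code{trait_matrix}: the data.frame with a \code{state_spaces}
#'   attribute.
#' @export
trait_matrix <- function(data, state_spaces = NULL) {
  stopifnot(is.data.frame(data), !is.null(rownames(data)))
  data[] <- lapply(data, as.character)
  if (is.null(state_spaces)) state_spaces <- list()
  for (ch in names(data)) {
    observed <- setdiff(unique(data[[ch]]), MISSING_SYMBOL)
    if (is.null(state_spaces[[ch]])) {
      state_spaces[[ch]] <- sort(observed)
    } else {
      bad <- setdiff(observed, state_spaces[[ch]])
      if (length(bad))
        stop("unknown state symbol '", bad[1L], "' in character '", ch, "'")
    }
  }
  structure(data, state_spaces = state_spaces[names(data)],
            class = c("trait_matrix", "data.frame"))
}

#' Read a trait matrix from TSV/CSV or a NEXUS characters block
#'
#' Tabular input has a header row of character names and taxon names in the
#' first column. A sidecar state-space file (TSV with columns
#' \code{character}, \code{states} -- comma-separated symbols) pins the state
#' spaces; otherwise they are inferred from the observed symbols, with
#' \code{"?"} flagged missing and excluded from inference.
#'
#' @param file Path to a TSV/CSV file or a NEXUS file (detected by the
#'   leading \code{#NEXUS}).
#' @param states_file Optional sidecar state-space declaration (TSV input
#'   only).
#' @return A \code{trait_matrix}.
#' @export
read_traits <- function(file, states_file = NULL) {
  first <- readLines(file, n = 1L)
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
    raw <- ape::read.nexus.data(file)
    m <- do.call(rbind, lapply(raw, function(x) toupper(unlist(x))))
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- paste0("char", seq_len(ncol(df)))
    return(trait_matrix(df))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("trait file needs a taxon column plus >=1 character")
  rn <- df[[1L]]
  if (anyDuplicated(rn)) stop("duplicate taxon name: ", rn[duplicated(rn)][1L])
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- rn
  spaces <- NULL
  if (!is.null(states_file)) {
    sdf <- utils::read.table(states_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    spaces <- lapply(strsplit(sdf$states, ","), trimws)
    names(spaces) <- sdf$character
  }
  trait_matrix(df, spaces)
}

#' Write a trait matrix (TSV plus sidecar state-space file)
#' @param traits A \code{trait_matrix}.
#' @param file Output TSV path; the sidecar goes to \code{<file>.states}.
#' @return \code{file}, invisibly.
#' @export
write_traits <- function(traits, file) {
  df <- cbind(taxon = rownames(traits), as.data.frame(traits))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- attr(traits, "state_spaces")
  sdf <- data.frame(character = names(sp),
                    states = vapply(sp, paste, "", collapse = ","))
  utils::write.table(sdf, paste0(file, ".states"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Extract one character as a named vector (taxon -> symbol), checking
# tree/trait taxon agreement. Tips absent from the matrix become "?".
#' @keywords internal
.trait_column <- function(traits, character, tree = NULL) {
  if (!character %in% names(traits))
    stop("no character named '", character, "'")
  x <- stats::setNames(traits[[character]], rownames(traits))
  if (!is.null(tree)) {
    miss <- setdiff(tree$tip.label, names(x))
    x <- c(x, stats::setNames(rep(MISSING_SYMBOL, length(miss)), miss))
    x <- x[tree$tip.label]
  }
  attr(x, "states") <- attr(traits, "state_spaces")[[character]]
  x
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", nrow(x), "taxa x", ncol(x), "characters\n")
  sp <- attr(x, "state_spaces")
  for (ch in names(sp))
    cat("  ", ch, ": {", paste(sp[[ch]], collapse = ", "), "}\n", sep = "")
  invisible(x)
}
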