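# Minimal FASTA reader/writer. Case is preserved exactly (percent-identity
# conventions are case-sensitive in some pipelines), which is why this does
# not round-trip through a biological sequence class.

#' Read a FASTA file
#'
#' @param file Path.
#' @param to_dna Convert U/u to T/t (RNA input for a DNA comparison)?
#' @return Named character vector of sequences, in file order, case
#'   preserved.
#' @export
read_fasta <- function(file, to_dna = FALSE) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop("not FASTA: first line must start '>'")
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop("duplicate sequence name: ", names_[duplicated(names_)][1L])
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  if (length(seqs) != length(names_) || any(!nzchar(seqs)))
    stop("empty FASTA record: ",
         names_[!names_ %in% names_[seq_along(seqs)][nzchar(seqs)]][1L])
  names(seqs) <- names_
  if (to_dna) seqs <- chartr("Uu", "Tt", seqs)
  seqs
}

#' Write sequences as FASTA
#' @param seqs Named character vector.
#' @param file Output path.
#' @param width Line-wrap width.
#' @return \code{file}, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}
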