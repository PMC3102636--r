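# ---- FASTA output -----------------------------------------------------------

#' Write sequences to a FASTA file
#'
#' Records are wrapped at `width` characters per line; gapped alignment rows
#' use `-` as the gap character, so the output is readable by any standard
#' FASTA parser.
#'
#' @param sequences named character vector (one string per record).
#' @param path output file.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
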