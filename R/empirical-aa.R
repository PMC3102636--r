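# ---- empirical amino-acid models ------------------------------------------
#
# Empirical models are specified by a symmetric exchangeability matrix S and
# equilibrium frequencies pi, with Q_ij = S_ij * pi_j. WAG, JTT and LG are
# available by name (served from phangorn's model collection); any other
# matrix can be read from the standard plain-text exchangeability layout
# (lower-triangular 19-row block of 190 values followed by 20 frequencies,
# '#' comments allowed) used by most phylogenetics software.

#' Empirical amino-acid substitution model
#'
#' @param source `"WAG"`, `"JTT"` or `"LG"`, or the path of an
#'   exchangeability file (lower-triangle block + frequencies; amino acids
#'   in the order A R N D C Q E G H I L K M F P S T W Y V).
#' @return a normalized 20-state `gs_model`.
#' @examples
#' m <- empirical_aa_model("WAG")
#' range(rowSums(m$Q))  # ~0
#' @export
empirical_aa_model <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (toupper(source) %in% c("WAG", "JTT", "LG")) {
    obj <- get(paste0(".", toupper(source)), envir = asNamespace("phangorn"))
    s <- obj$Q   # 190 lower-triangle exchangeabilities, PAML row order
    pi <- as.numeric(obj$bf)
    label <- toupper(source)
  } else {
    if (!file.exists(source)) {
      stop("unknown model name or missing file: ", source, call. = FALSE)
    }
    parsed <- read_exchangeability_file(source)
    s <- parsed$exchangeabilities
    pi <- parsed$frequencies
    label <- basename(source)
  }
  build_aa_model(s, pi, label)
}

build_aa_model <- function(s, pi, label) {
  ab <- amino_acid_alphabet()
  S <- matrix(0, 20, 20, dimnames = list(ab$symbols, ab$symbols))
  S[upper.tri(S)] <- 0
  k <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    S[i, j] <- s[k]; k <- k + 1L
  }
  S <- S + t(S)
  if (abs(sum(pi) - 1) > 1e-8) {
    warning("frequencies sum to ", format(sum(pi), digits = 8),
            "; renormalizing")
    pi <- pi / sum(pi)
  }
  R <- S * rep(pi, each = 20)
  general_model(ab, R, pi = pi, label = label)
}

#' Read / write the standard amino-acid exchangeability file format
#'
#' The format is 19 rows of the lower triangle of the symmetric
#' exchangeability matrix (row i holds i values), followed by the 20
#' equilibrium frequencies. Tokens are whitespace-separated; lines starting
#' with `#` (or trailing `#` comments) are ignored.
#'
#' @param path file path.
#' @return for the reader, a list with `exchangeabilities` (length 190, row
#'   order) and `frequencies` (length 20).
#' @export
read_exchangeability_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  vals <- numeric(0)
  expected <- c(1:19, 20)  # triangle rows then the frequency row
  row_i <- 1L
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    x <- suppressWarnings(as.numeric(toks))
    if (anyNA(x)) {
      stop("non-numeric token on line ", ln, " of ", path, call. = FALSE)
    }
    if (row_i <= length(expected) && length(x) != expected[row_i]) {
      stop("malformed exchangeability file ", path, ": line ", ln,
           " has ", length(x), " values, expected ", expected[row_i],
           call. = FALSE)
    }
    if (row_i > length(expected)) {
      stop("malformed exchangeability file ", path,
           ": unexpected extra values on line ", ln, call. = FALSE)
    }
    vals <- c(vals, x)
    row_i <- row_i + 1L
  }
  if (length(vals) != 210L) {
    stop("malformed exchangeability file ", path, ": found ", length(vals),
         " values, expected 210 (190 exchangeabilities + 20 frequencies)",
         call. = FALSE)
  }
  list(exchangeabilities = vals[1:190], frequencies = vals[191:210])
}

#' @rdname read_exchangeability_file
#' @param model a 20-state `gs_model` built from exchangeabilities.
#' @export
write_exchangeability_file <- function(model, path) {
  stopifnot(inherits(model, "gs_model"),
            length(model$alphabet$symbols) == 20L)
  # recover S_ij = Q_ij / pi_j (defined up to overall scale)
  S <- sweep(model$Q, 2, model$pi, "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", model$label, "exchangeabilities + frequencies"), con)
  for (i in 2:20) {
    writeLines(paste(format(S[i, 1:(i - 1)], digits = 10, trim = TRUE),
                     collapse = " "), con)
  }
  writeLines(paste(format(as.numeric(model$pi), digits = 10, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}
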