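# ---- parameter-recovery diagnostics --------------------------------------------
#
# Closed-form estimators used to validate the simulator by recovering the
# parameters it was run with; no external ML software is involved.

#' Proportion of differing homologous sites (p-distance)
#'
#' Sites where either sequence has a gap (`-` of any width, or `NA` as in
#' true-alignment token rows) are excluded; the comparison runs over the
#' remaining shared columns, which must exist.
#'
#' @param a,b token vectors (or single strings, split into characters) of
#'   equal length — typically two rows of a true alignment or two ungapped
#'   tip sequences.
#' @return fraction of compared sites that differ.
#' @export
p_distance <- function(a, b) {
  a <- as_tokens(a); b <- as_tokens(b)
  if (length(a) != length(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  cmp <- !is.na(a) & !is.na(b) & !grepl("^-+$", a) & !grepl("^-+$", b)
  if (!any(cmp)) stop("no comparable (ungapped) sites", call. = FALSE)
  sum(a[cmp] != b[cmp]) / sum(cmp)
}

as_tokens <- function(x) {
  if (length(x) == 1L && !is.na(x) && nchar(x) > 1L) strsplit(x, "")[[1]]
  else as.character(x)
}

#' Transition / transversion difference fractions of a nucleotide pair
#'
#' @param a,b aligned nucleotide token vectors (or strings); gap sites are
#'   excluded.
#' @return list with `P` (fraction of sites differing by a transition),
#'   `Q` (by a transversion) and `n` (compared sites).
#' @export
pq_fractions <- function(a, b) {
  a <- as_tokens(a); b <- as_tokens(b)
  if (length(a) != length(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  cmp <- !is.na(a) & !is.na(b) &
    a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(cmp)) stop("no comparable sites", call. = FALSE)
  a <- a[cmp]; b <- b[cmp]
  diff <- a != b
  ts <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                (a %in% c("C", "T") & b %in% c("C", "T")))
  list(P = sum(ts) / length(a), Q = sum(diff & !ts) / length(a),
       n = length(a))
}

#' K80 distance and kappa estimators
#'
#' Closed-form estimators from the transition (`P`) and transversion (`Q`)
#' difference fractions of an aligned pair:
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4` and
#' `kappa = 2 * (-log(1 - 2P - Q)/2 + log(1 - 2Q)/4) / (-log(1 - 2Q)/2)`
#' (the instantaneous transition/transversion rate ratio). Feeding the
#' exact `P`, `Q` from [transition_probabilities()] of a K80 model returns
#' the true `(d, kappa)` to numerical precision.
#'
#' @param P,Q difference fractions, with `1 - 2P - Q > 0` and `1 - 2Q > 0`
#'   (otherwise the pair is saturated and an error is raised).
#' @return list with `d` (expected substitutions per site) and `kappa_hat`.
#' @export
k80_estimates <- function(P, Q) {
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    stop("saturation: log-domain violation (1-2P-Q and 1-2Q must be > 0)",
         call. = FALSE)
  }
  A <- -0.5 * log(1 - 2 * P - Q)
  B4 <- -0.25 * log(1 - 2 * Q)
  d <- A + B4
  kappa_hat <- 2 * (A - B4) / (2 * B4)
  list(d = d, kappa_hat = kappa_hat)
}

#' Tally events in a simulation log
#'
#' @param events event-log data frame (from [evolve_branch()] or
#'   [simulate_evolution()]).
#' @param code optional genetic code; when given, substitutions whose detail
#'   is a codon change (`XXX->YYY`) are additionally classified as
#'   synonymous or nonsynonymous.
#' @return named list of counts: `substitutions`, `insertions_proposed`,
#'   `insertions_accepted`, `deletions_proposed`, `deletions_accepted`,
#'   and with `code`, `synonymous` / `nonsynonymous`.
#' @export
count_events <- function(events, code = NULL) {
  out <- list(
    substitutions = sum(events$kind == "substitution"),
    insertions_proposed = sum(events$kind == "insertion"),
    insertions_accepted = sum(events$kind == "insertion" & events$accepted),
    deletions_proposed = sum(events$kind == "deletion"),
    deletions_accepted = sum(events$kind == "deletion" & events$accepted)
  )
  if (!is.null(code)) {
    det <- events$detail[events$kind == "substitution"]
    codonish <- grepl("^[ACGT]{3}->[ACGT]{3}$", det)
    from <- substr(det[codonish], 1, 3)
    to <- substr(det[codonish], 6, 8)
    syn <- code[from] == code[to]
    out$synonymous <- sum(syn)
    out$nonsynonymous <- sum(!syn)
  }
  out
}
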