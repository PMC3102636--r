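# ---- insertion and deletion processes ---------------------------------------
#
# Deletions follow a "field" model: a deletion of length drawn from the
# process's length distribution is proposed at a per-site initiation rate;
# the span covers the initiating site and its right neighbours and is
# accepted with probability prod(d_i) over the span's per-site deletion
# tolerances (d = 1: background rate, d = 0: never deleted). The fast-field
# variant rescales the proposal rate by D, the maximum tolerance among the
# bound sites, and divides the acceptance product by D once, so the realized
# per-span deletion rate (proposal rate x acceptance probability) is exactly
# the plain-field one while far fewer proposals are wasted when the sequence
# is strongly deletion-intolerant.

#' Indel length distributions
#'
#' All distributions put their mass on integer lengths >= 1.
#' `fixed_length(k)` is a point mass; `geometric_length(p)` is 1 + a
#' geometric count of failures (mean `1/p`); `poisson_length(lambda)` is a
#' shifted Poisson `1 + Pois(lambda)`; `table_length(lengths, probs)` is an
#' arbitrary finite table (probabilities must sum to 1); `user_length(fn)`
#' wraps any sampler `fn(n)` returning `n` integer lengths >= 1, so any R
#' expression or distribution can drive indel lengths.
#'
#' @param k,p,lambda,lengths,probs,fn distribution parameters.
#' @return an object of class `gs_length_dist`.
#' @name length_distributions
NULL

#' @rdname length_distributions
#' @export
fixed_length <- function(k) {
  k <- as.integer(k)
  if (k < 1L) stop("fixed length must be >= 1", call. = FALSE)
  structure(list(kind = "fixed", k = k), class = "gs_length_dist")
}

#' @rdname length_distributions
#' @export
geometric_length <- function(p) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  structure(list(kind = "geometric", p = p), class = "gs_length_dist")
}

#' @rdname length_distributions
#' @export
poisson_length <- function(lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(kind = "poisson_shifted", lambda = lambda),
            class = "gs_length_dist")
}

#' @rdname length_distributions
#' @export
table_length <- function(lengths, probs) {
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("lengths must be >= 1", call. = FALSE)
  if (length(lengths) != length(probs) || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-9) {
    stop("probs must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(list(kind = "user_table", lengths = lengths, probs = probs),
            class = "gs_length_dist")
}

#' @rdname length_distributions
#' @export
user_length <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(kind = "callable", fn = fn), class = "gs_length_dist")
}

#' Sample indel lengths
#'
#' @param dist a `gs_length_dist`.
#' @param n number of draws.
#' @return integer vector of lengths >= 1; deterministic given the RNG
#'   state.
#' @export
sample_indel_length <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "gs_length_dist"))
  out <- switch(dist$kind,
    fixed = rep(dist$k, n),
    geometric = 1L + stats::rgeom(n, dist$p),
    poisson_shifted = 1L + stats::rpois(n, dist$lambda),
    user_table = if (length(dist$lengths) == 1L) {
      rep(dist$lengths, n)
    } else {
      sample(dist$lengths, n, replace = TRUE, prob = dist$probs)
    },
    callable = {
      v <- dist$fn(n)
      if (any(v < 1) || any(v != round(v))) {
        stop("user length sampler returned a length < 1 or non-integer",
             call. = FALSE)
      }
      v
    }
  )
  as.integer(out)
}

#' Deletion process
#'
#' @param rate nonnegative per-site proposal initiation rate, relative to
#'   the substitution time unit (expected substitutions per site).
#' @param lengths a length distribution, see [length_distributions].
#' @param mode `"plain_field"` proposes at the background rate and accepts
#'   with `prod(d_i)`; `"fast_field"` proposes at `rate * D` (D = maximum
#'   tolerance among bound sites) and accepts with `prod(d_i) / D` — the
#'   same realized deletion rate with fewer rejected proposals.
#' @param label free text used in logs.
#' @return an object of class `gs_deletion_process`.
#' @export
deletion_process <- function(rate, lengths = fixed_length(1L),
                             mode = c("plain_field", "fast_field"),
                             label = "deletion") {
  if (!is.numeric(rate) || rate < 0) {
    stop("deletion rate must be >= 0", call. = FALSE)
  }
  mode <- match.arg(mode)
  stopifnot(inherits(lengths, "gs_length_dist"))
  structure(list(rate = rate, lengths = lengths, mode = mode,
                 label = label, pid = next_pid("del")),
            class = "gs_deletion_process")
}

#' Insertion process
#'
#' New sites are produced by `generator(length, context, seq)`, which must
#' return `list(states = <length tokens>, bindings = <length binding
#' lists>)`. `context` is a list with `position` (the initiating site, the
#' insert goes immediately to its right), `left` and `right` (flanking
#' tokens), giving full control over inserted sequences (e.g. duplications
#' copying the flank). The default generator draws states from the template
#' model's equilibrium frequencies and binds inserted sites to the template
#' processes, with fresh multipliers from the template rate model.
#'
#' @param rate nonnegative per-site initiation rate.
#' @param lengths a length distribution, see [length_distributions].
#' @param generator custom site generator, or `NULL` for the default.
#' @param template list describing default bindings of inserted sites:
#'   `model` (substitution model, required unless a custom generator is
#'   given), `rate_model` (optional [site_rate_model()]),
#'   `deletion_tolerance`, `insertion_tolerance`, `label`.
#' @param label free text used in logs.
#' @return an object of class `gs_insertion_process`.
#' @export
insertion_process <- function(rate, lengths = fixed_length(1L),
                              generator = NULL, template = list(),
                              label = "insertion") {
  if (!is.numeric(rate) || rate < 0) {
    stop("insertion rate must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(lengths, "gs_length_dist"))
  if (is.null(generator) && is.null(template$model)) {
    stop("insertion_process needs a template$model or a custom generator",
         call. = FALSE)
  }
  proc <- structure(list(rate = rate, lengths = lengths,
                         generator = generator, template = template,
                         label = label, pid = next_pid("ins")),
                    class = "gs_insertion_process")
  proc
}

# default insert generator: equilibrium states + template bindings
default_insert_sites <- function(proc, length, context, seq) {
  tpl <- proc$template
  model <- tpl$model
  states <- sample(model$alphabet$symbols, length, replace = TRUE,
                   prob = model$pi)
  rm <- if (is.null(tpl$rate_model)) {
    rep(1, length)
  } else {
    draw_site_rates(tpl$rate_model, length)
  }
  dt <- if (is.null(tpl$deletion_tolerance)) 1 else tpl$deletion_tolerance
  it <- if (is.null(tpl$insertion_tolerance)) 1 else tpl$insertion_tolerance
  bindings <- lapply(seq_len(length), function(i) {
    bl <- list(new_binding(model, rm = rm[i], dt = dt, it = it))
    # extra_processes lets the template re-bind indel processes so that
    # inserted sites themselves stay subject to insertion/deletion
    for (extra in tpl$extra_processes %||% list()) {
      bl <- c(bl, list(new_binding(extra, rm = 1, dt = dt, it = it)))
    }
    bl
  })
  list(states = states, bindings = bindings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duplication insert generator
#'
#' Returns a generator that copies the tokens (and bindings) of the sites
#' immediately left of the insertion point — a tandem duplication. If the
#' left flank is shorter than the drawn length the copied block is truncated
#' to the available flank.
#'
#' @return a generator function for [insertion_process()].
#' @export
duplication_generator <- function() {
  function(length, context, seq) {
    pos <- context$position
    from <- max(1L, pos - length + 1L)
    idx <- from:pos
    list(states = seq$states[idx], bindings = seq$bindings[idx])
  }
}

#' Propose a deletion span
#'
#' The span starts at the initiating site and extends rightward by the
#' drawn length; spans overrunning the sequence end are truncated (never
#' rejected), so no artificial edge effect is introduced. Spans may cross
#' partition boundaries freely.
#'
#' @param seq a `gs_sequence`.
#' @param proc a `gs_deletion_process`.
#' @param initiating_site 1-based site index where the proposal initiates.
#' @param length optional pre-drawn length (drawn from `proc$lengths` if
#'   `NULL`).
#' @return an object of class `gs_deletion_span`: `from`, `to` (inclusive),
#'   `initiating_site`, `proposed_length`, `truncated`.
#' @export
propose_deletion <- function(seq, proc, initiating_site, length = NULL) {
  n <- base::length(seq$states)
  if (initiating_site < 1L || initiating_site > n) {
    stop("initiating site out of bounds", call. = FALSE)
  }
  len <- if (is.null(length)) sample_indel_length(proc$lengths) else
    as.integer(length)
  to <- initiating_site + len - 1L
  truncated <- to > n
  if (truncated) to <- n
  structure(list(from = initiating_site, to = to,
                 initiating_site = initiating_site,
                 proposed_length = len, truncated = truncated),
            class = "gs_deletion_span")
}

# deletion tolerance of a site with respect to a process; sites with no
# binding to the process are neutral (d = 1)
deletion_tolerances <- function(seq, span, proc) {
  idx <- span$from:span$to
  vapply(idx, function(i) {
    for (b in seq$bindings[[i]]) {
      if (identical(b$proc$pid, proc$pid)) return(b$dt)
    }
    1
  }, numeric(1))
}

#' Acceptance probability of a proposed deletion
#'
#' Plain field: `prod(d_i)` over the span. Fast field: `prod(d_i) / D`
#' where `D` is the maximum deletion tolerance among sites bound to the
#' process; since every `d_i <= D`, the ratio never exceeds 1.
#'
#' @param seq a `gs_sequence`.
#' @param span a `gs_deletion_span` from [propose_deletion()].
#' @param proc the proposing `gs_deletion_process`.
#' @return acceptance probability in `[0, 1]`.
#' @export
deletion_acceptance_probability <- function(seq, span, proc) {
  d <- deletion_tolerances(seq, span, proc)
  p <- prod(d)
  if (proc$mode == "fast_field") {
    D <- fast_field_D(seq, proc)
    if (D <= 0) return(0)
    p <- p / D
  }
  min(p, 1)
}

#' Effective deletion proposal rate at a site
#'
#' Plain field: `rate * rate_multiplier`. Fast field:
#' `rate * rate_multiplier * D` with `D` the current maximum deletion
#' tolerance among bound sites (with all tolerances 0 no proposal ever
#' fires).
#'
#' @inheritParams deletion_acceptance_probability
#' @param i site index, which must be bound to `proc`.
#' @return nonnegative proposal rate.
#' @export
effective_deletion_proposal_rate <- function(seq, proc, i) {
  for (b in seq$bindings[[i]]) {
    if (identical(b$proc$pid, proc$pid)) {
      r <- b$rm * proc$rate
      if (proc$mode == "fast_field") r <- r * fast_field_D(seq, proc)
      return(r)
    }
  }
  stop("site ", i, " is not bound to the deletion process", call. = FALSE)
}

#' Accept or reject a proposed event
#'
#' A rejected event still consumes its Gillespie time step: rejection is
#' how selective constraints slow a process down, not a re-draw.
#'
#' @param probability acceptance probability in `[0, 1]`.
#' @return `TRUE` with the given probability; deterministic given the RNG
#'   state (consumes exactly one uniform draw).
#' @export
accept_or_reject <- function(probability) {
  if (!is.numeric(probability) || is.na(probability) ||
      probability < 0 || probability > 1) {
    stop("acceptance probability must be in [0, 1]", call. = FALSE)
  }
  u <- stats::runif(1)
  u < probability || probability >= 1
}

#' Propose an insertion
#'
#' Draws a length, invokes the process's generator with the flanking
#' context, and validates the produced sites. The insertion point is
#' immediately right of the initiating site; insertions before the first
#' site are not modelled.
#'
#' @param seq a `gs_sequence`.
#' @param proc a `gs_insertion_process`.
#' @param initiating_site 1-based index of the initiating site.
#' @param length optional pre-drawn length.
#' @param flank number of flanking tokens passed in the context.
#' @return list with `at` (insert goes right of this index), `states`,
#'   `bindings`.
#' @export
propose_insertion <- function(seq, proc, initiating_site, length = NULL,
                              flank = 10L) {
  n <- base::length(seq$states)
  if (initiating_site < 1L || initiating_site > n) {
    stop("initiating site out of bounds", call. = FALSE)
  }
  len <- if (is.null(length)) sample_indel_length(proc$lengths) else
    as.integer(length)
  context <- list(
    position = initiating_site,
    left = seq$states[max(1L, initiating_site - flank + 1L):initiating_site],
    right = if (initiating_site < n) {
      seq$states[(initiating_site + 1L):min(n, initiating_site + flank)]
    } else character(0)
  )
  gen <- proc$generator %||% function(length, context, seq) {
    default_insert_sites(proc, length, context, seq)
  }
  out <- gen(len, context, seq)
  if (!is.list(out) || is.null(out$states) || is.null(out$bindings) ||
      base::length(out$states) != len ||
      base::length(out$bindings) != len) {
    stop("insertion generator '", proc$label,
         "' returned an invalid payload (need 'states' and 'bindings' of ",
         "length ", len, ")", call. = FALSE)
  }
  for (k in seq_len(len)) {
    for (b in out$bindings[[k]]) {
      if (inherits(b$proc, "gs_model") &&
          !(out$states[k] %in% b$proc$alphabet$symbols)) {
        stop("insertion generator '", proc$label, "' produced state '",
             out$states[k], "' outside the alphabet of its bound process",
             call. = FALSE)
      }
    }
  }
  list(at = initiating_site, states = as.character(out$states),
       bindings = out$bindings)
}

# insertion tolerance of the initiating site w.r.t. the process (single
# flank rule: only the initiating site gates the insertion)
insertion_tolerance_at <- function(seq, proc, i) {
  for (b in seq$bindings[[i]]) {
    if (identical(b$proc$pid, proc$pid)) return(b$it)
  }
  1
}
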