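# ---- the evolving sequence --------------------------------------------------
#
# An EvolvingSequence is a mutable environment holding, per site:
#   states[i]    token (from the alphabet of the site's substitution
#                process(es), or an arbitrary fixed motif token)
#   ids[i]       unique site identity, threading homology through indels
#   labels[i]    partition label (annotation only)
#   bindings[[i]] list of process bindings; each binding is
#                list(proc, rm, dt, it): the process object, the site- and
#                process-specific rate multiplier, deletion tolerance and
#                insertion tolerance
# plus cached per-site total event rates and their sum. Substitutions update
# the cache in O(1); indels and property edits trigger a full recompute
# (they also invalidate the fast-field maximum-tolerance cache).

new_sequence_env <- function(states, bindings, labels = NULL,
                             ids = seq_along(states)) {
  e <- new.env(parent = emptyenv())
  e$states <- as.character(states)
  e$ids <- as.integer(ids)
  e$labels <- if (is.null(labels)) rep(NA_character_, length(states)) else labels
  e$bindings <- bindings
  e$rates <- numeric(length(states))
  e$total_rate <- 0
  e$D_cache <- list()
  e$next_id <- if (length(ids)) max(ids) + 1L else 1L
  e$bver <- 0L     # binding-structure version; bumped on any binding change
  e$fp <- NULL     # vectorized rate fast path (see recompute_rates)
  e$uniform <- FALSE
  class(e) <- "gs_sequence"
  recompute_rates(e)
  e
}

#' @export
print.gs_sequence <- function(x, ...) {
  cat("<evolving sequence: ", length(x$states), " sites, total rate ",
      format(x$total_rate, digits = 6), ">\n", sep = "")
  invisible(x)
}

#' Length and states of an evolving sequence
#'
#' @param seq a `gs_sequence`.
#' @return `sequence_tokens` returns the character vector of site tokens;
#'   `sequence_length` the number of sites.
#' @export
sequence_tokens <- function(seq) seq$states

#' @rdname sequence_tokens
#' @export
sequence_length <- function(seq) length(seq$states)

new_binding <- function(proc, rm = 1, dt = 1, it = 1) {
  list(proc = proc, rm = rm, dt = dt, it = it)
}

#' Create a root sequence at equilibrium
#'
#' Site states are drawn independently from the model's stationary
#' distribution; every site gets one binding to `model` with a rate
#' multiplier drawn from `rate_model` (1 if omitted) and neutral indel
#' tolerances. Deterministic given the RNG state.
#'
#' @param length number of sites (>= 1). For codon models a site is a codon.
#' @param model a `gs_model` substitution process.
#' @param rate_model optional [site_rate_model()] for per-site multipliers.
#' @param deletion_tolerance,insertion_tolerance defaults stored on the
#'   substitution binding (meaningful once indel processes are attached
#'   with [attach_process()], which carries its own tolerances).
#' @param label partition label recorded on the sites (annotation only).
#' @return a `gs_sequence`.
#' @export
root_sequence <- function(length, model, rate_model = NULL,
                          deletion_tolerance = 1, insertion_tolerance = 1,
                          label = NA_character_) {
  stopifnot(inherits(model, "gs_model"))
  n <- as.integer(length)
  if (n < 1L) stop("length must be >= 1", call. = FALSE)
  states <- sample(model$alphabet$symbols, n, replace = TRUE,
                   prob = model$pi)
  rm <- if (is.null(rate_model)) rep(1, n) else draw_site_rates(rate_model, n)
  bindings <- lapply(seq_len(n), function(i) {
    list(new_binding(model, rm = rm[i], dt = deletion_tolerance,
                     it = insertion_tolerance))
  })
  new_sequence_env(states, bindings, labels = rep(label, n))
}

#' Create a root sequence from explicit tokens
#'
#' Builds a sequence with exactly the given states. With `model = NULL` the
#' sites carry no substitution binding and never change state (fixed motifs
#' such as start codons or splice sites); indel processes may still be
#' attached to them later.
#'
#' @param tokens a character vector of tokens, or a single string which is
#'   split into tokens of the model's token width (1 if no model).
#' @param model optional `gs_model` bound to every site; each token must
#'   belong to its alphabet.
#' @inheritParams root_sequence
#' @return a `gs_sequence`.
#' @export
root_sequence_from_string <- function(tokens, model = NULL,
                                      rate_model = NULL,
                                      deletion_tolerance = 1,
                                      insertion_tolerance = 1,
                                      label = NA_character_) {
  if (length(tokens) == 1L && !is.null(model) &&
      nchar(tokens) > alphabet_width(model$alphabet)) {
    tokens <- chunk_string(tokens, alphabet_width(model$alphabet))
  } else if (length(tokens) == 1L && is.null(model) && nchar(tokens) > 1L) {
    tokens <- strsplit(tokens, "")[[1]]
  }
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (n < 1L) stop("need at least one token", call. = FALSE)
  if (!is.null(model)) {
    bad <- which(!(tokens %in% model$alphabet$symbols))
    if (length(bad)) {
      stop("token '", tokens[bad[1]], "' at site ", bad[1],
           " is not in the model's alphabet", call. = FALSE)
    }
    rm <- if (is.null(rate_model)) rep(1, n) else draw_site_rates(rate_model, n)
    bindings <- lapply(seq_len(n), function(i) {
      list(new_binding(model, rm = rm[i], dt = deletion_tolerance,
                       it = insertion_tolerance))
    })
  } else {
    bindings <- rep(list(list()), n)
  }
  new_sequence_env(tokens, bindings, labels = rep(label, n))
}

chunk_string <- function(s, w) {
  n <- nchar(s)
  if (n %% w != 0) {
    stop("string length ", n, " is not a multiple of token width ", w,
         call. = FALSE)
  }
  substring(s, seq(1, n, w), seq(w, n, w))
}

#' Concatenate evolving sequences into one
#'
#' Joins partitions (each typically built with [root_sequence()] or
#' [root_sequence_from_string()]) into a single root sequence; site
#' identities are renumbered left to right. Deletion spans are free to cross
#' the junctions: partitions do not constrain indels.
#'
#' @param ... `gs_sequence` objects, left to right.
#' @return a `gs_sequence`.
#' @export
concat_sequences <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "gs_sequence")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "gs_sequence")))
  states <- unlist(lapply(parts, function(p) p$states))
  labels <- unlist(lapply(parts, function(p) p$labels))
  bindings <- do.call(c, lapply(parts, function(p) p$bindings))
  new_sequence_env(states, bindings, labels = labels)
}

# independent copy (children of a node evolve independent copies)
clone_sequence <- function(seq) {
  e <- new.env(parent = emptyenv())
  for (nm in c("states", "ids", "labels", "bindings", "rates",
               "total_rate", "D_cache", "next_id", "bver", "fp",
               "uniform")) {
    assign(nm, get(nm, envir = seq), envir = e)
  }
  class(e) <- "gs_sequence"
  e
}

#' Attach a process to a range of sites
#'
#' Appends a binding of `proc` (a substitution model, [deletion_process()]
#' or [insertion_process()]) to every site in `from:to`, with the given
#' site-specific parameters, and refreshes the cached event rates. Several
#' substitution processes may act on the same site provided they share an
#' alphabet. An empty range (`from > to`) is a no-op.
#'
#' @param seq a `gs_sequence` (modified in place).
#' @param from,to inclusive 1-based site range.
#' @param proc the process to bind.
#' @param rate_multiplier nonnegative multiplier(s), scalar or one per site.
#' @param deletion_tolerance,insertion_tolerance tolerances in `[0, 1]`,
#'   scalar or one per site.
#' @return the sequence, invisibly.
#' @export
attach_process <- function(seq, from, to, proc, rate_multiplier = 1,
                           deletion_tolerance = 1, insertion_tolerance = 1) {
  stopifnot(inherits(seq, "gs_sequence"))
  from <- as.integer(from); to <- as.integer(to)
  if (from > to) return(invisible(seq))
  n <- length(seq$states)
  if (from < 1L || to > n) {
    stop("range [", from, ", ", to, "] outside sequence of length ", n,
         call. = FALSE)
  }
  idx <- from:to
  k <- length(idx)
  rm <- rep_len(rate_multiplier, k)
  dt <- rep_len(deletion_tolerance, k)
  it <- rep_len(insertion_tolerance, k)
  check_property("rate_multiplier", rm)
  check_property("deletion_tolerance", dt)
  check_property("insertion_tolerance", it)
  if (inherits(proc, "gs_model")) {
    for (i in idx) {
      if (!(seq$states[i] %in% proc$alphabet$symbols)) {
        stop("state '", seq$states[i], "' at site ", i,
             " is not in the alphabet of process '", proc$label, "'",
             call. = FALSE)
      }
      for (b in seq$bindings[[i]]) {
        if (inherits(b$proc, "gs_model") &&
            !identical(b$proc$alphabet$symbols, proc$alphabet$symbols)) {
          stop("site ", i, " already bound to a substitution process over ",
               "a different alphabet", call. = FALSE)
        }
      }
    }
  }
  bnd <- seq$bindings
  for (j in seq_along(idx)) {
    i <- idx[j]
    bnd[[i]] <- c(bnd[[i]], list(new_binding(proc, rm[j], dt[j], it[j])))
  }
  seq$bindings <- bnd
  seq$bver <- seq$bver + 1L
  recompute_rates(seq)
  invisible(seq)
}

check_property <- function(key, value) {
  if (key == "rate_multiplier") {
    if (any(value < 0)) stop("rate_multiplier must be >= 0", call. = FALSE)
  } else {
    if (any(value < 0 | value > 1)) {
      stop(key, " must be in [0, 1]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Set a site- and process-specific property
#'
#' Updates `rate_multiplier`, `deletion_tolerance` or `insertion_tolerance`
#' on the binding of `proc` at site `i` and refreshes cached rates. This is
#' the mutator used by node hooks to implement heterotachy and changing
#' indel constraints.
#'
#' @param seq a `gs_sequence` (modified in place).
#' @param i site index (1-based), may be a vector.
#' @param proc the bound process whose parameters are edited.
#' @param key one of `"rate_multiplier"`, `"deletion_tolerance"`,
#'   `"insertion_tolerance"`.
#' @param value new value(s), recycled over `i`.
#' @return the sequence, invisibly.
#' @export
set_site_property <- function(seq, i, proc,
                              key = c("rate_multiplier",
                                      "deletion_tolerance",
                                      "insertion_tolerance"),
                              value) {
  stopifnot(inherits(seq, "gs_sequence"))
  key <- match.arg(key)
  i <- as.integer(i)
  n <- length(seq$states)
  if (any(i < 1L | i > n)) stop("site index out of bounds", call. = FALSE)
  value <- rep_len(as.numeric(value), length(i))
  check_property(key, value)
  fld <- c(rate_multiplier = "rm", deletion_tolerance = "dt",
           insertion_tolerance = "it")[[key]]
  bnd <- seq$bindings
  for (j in seq_along(i)) {
    site <- i[j]
    found <- FALSE
    bl <- bnd[[site]]
    for (k in seq_along(bl)) {
      if (identical(bl[[k]]$proc$pid, proc$pid)) {
        bl[[k]][[fld]] <- value[j]
        found <- TRUE
      }
    }
    if (!found) {
      stop("site ", site, " has no binding to the given process",
           call. = FALSE)
    }
    bnd[[site]] <- bl
  }
  seq$bindings <- bnd
  seq$bver <- seq$bver + 1L
  recompute_rates(seq)
  invisible(seq)
}

#' Read back a site- and process-specific property
#'
#' @inheritParams set_site_property
#' @return numeric value of the property at site `i`.
#' @export
get_site_property <- function(seq, i, proc,
                              key = c("rate_multiplier",
                                      "deletion_tolerance",
                                      "insertion_tolerance")) {
  key <- match.arg(key)
  fld <- c(rate_multiplier = "rm", deletion_tolerance = "dt",
           insertion_tolerance = "it")[[key]]
  for (b in seq$bindings[[i]]) {
    if (identical(b$proc$pid, proc$pid)) return(b[[fld]])
  }
  stop("site ", i, " has no binding to the given process", call. = FALSE)
}

# ---- rate bookkeeping -------------------------------------------------------

# maximum deletion tolerance among sites currently bound to a fast-field
# deletion process ("most tolerant site"); cached per sequence
fast_field_D <- function(seq, proc) {
  cached <- seq$D_cache[[proc$pid]]
  if (!is.null(cached)) return(cached)
  D <- 0
  found <- FALSE
  for (bl in seq$bindings) {
    for (b in bl) {
      if (identical(b$proc$pid, proc$pid)) {
        found <- TRUE
        if (b$dt > D) D <- b$dt
      }
    }
  }
  if (!found) D <- 1  # no bound sites: scaling is irrelevant, stay neutral
  seq$D_cache[[proc$pid]] <- D
  D
}

# total event-initiation rate of one site, computed fresh from its bindings
compute_site_rate <- function(seq, i) {
  total <- 0
  state <- seq$states[i]
  for (b in seq$bindings[[i]]) {
    p <- b$proc
    if (inherits(p, "gs_model")) {
      total <- total + b$rm * -p$Q[p$alphabet$index[[state]],
                                   p$alphabet$index[[state]]]
    } else if (inherits(p, "gs_deletion_process")) {
      r <- b$rm * p$rate
      if (p$mode == "fast_field") r <- r * fast_field_D(seq, p)
      total <- total + r
    } else if (inherits(p, "gs_insertion_process")) {
      total <- total + b$rm * p$rate
    }
  }
  total
}

#' Event-initiation rate of a site
#'
#' The sum, over the site's process bindings, of the rate at which each
#' process initiates an event there: substitution leave-rate times the
#' multiplier, insertion initiation rate times the multiplier, and the
#' (plain or fast-field rescaled) deletion proposal rate times the
#' multiplier.
#'
#' @param seq a `gs_sequence`.
#' @param i site index (1-based).
#' @return nonnegative rate.
#' @export
site_event_rate <- function(seq, i) {
  stopifnot(inherits(seq, "gs_sequence"))
  if (i < 1L || i > length(seq$states)) {
    stop("site index out of bounds", call. = FALSE)
  }
  compute_site_rate(seq, i)
}

# full cache rebuild: drop fast-field caches, recompute every site rate.
# When every site carries a single binding to one shared substitution model
# (the most common layout) the rates are the model's leave rates indexed by
# state times the per-site multipliers; that structure is detected once per
# binding-structure version and rebuilt vectorized thereafter.
recompute_rates <- function(seq) {
  seq$D_cache <- list()
  n <- length(seq$states)
  if (n == 0L) {
    seq$rates <- numeric(0)
    seq$total_rate <- 0
    seq$uniform <- FALSE
    return(invisible(seq))
  }
  fp <- seq$fp
  if (is.null(fp) || fp$version != seq$bver) {
    fp <- build_fastpath(seq)
    seq$fp <- fp
  }
  if (isTRUE(fp$ok)) {
    r <- fp$rm * fp$leave[fp$index[seq$states]]
  } else {
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- compute_site_rate(seq, i)
  }
  seq$rates <- r
  seq$total_rate <- sum(r)
  rng <- range(r)
  seq$uniform <- rng[1] == rng[2]
  invisible(seq)
}

build_fastpath <- function(seq) {
  bad <- list(ok = FALSE, version = seq$bver)
  bl <- seq$bindings
  if (any(lengths(bl) != 1L)) return(bad)
  first <- bl[[1]][[1]]$proc
  if (!inherits(first, "gs_model")) return(bad)
  pid <- first$pid
  same <- vapply(bl, function(b) identical(b[[1]]$proc$pid, pid), logical(1))
  if (!all(same)) return(bad)
  list(ok = TRUE, version = seq$bver,
       rm = vapply(bl, function(b) b[[1]]$rm, numeric(1)),
       leave = -diag(first$Q), index = first$alphabet$index)
}

#' Total event rate of the sequence
#'
#' @param seq a `gs_sequence`.
#' @param recompute recompute from the bindings instead of returning the
#'   cache (used by the engine's periodic rate audit).
#' @return nonnegative total rate.
#' @export
total_event_rate <- function(seq, recompute = FALSE) {
  if (recompute) recompute_rates(seq)
  seq$total_rate
}
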