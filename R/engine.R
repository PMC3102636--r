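# ---- the Gillespie loop for one branch ---------------------------------------
#
# Exact stochastic simulation: the waiting time to the next event is
# exponential with rate equal to the sum of all event rates; the event is
# selected with probability proportional to its rate (hierarchically: site,
# then binding within the site, then the concrete change); indel events are
# then accepted or rejected — a rejected event consumes its time step. The
# loop stops when the next event would fall beyond the branch length.
#
# Frozen draw order (so a fixed seed reproduces a run exactly):
#   1. waiting time  2. site  3. binding (only if the site has > 1)
#   4. substitution target / indel length  5. acceptance uniform (indels)
#   6. insertion generator draws (only if accepted)

empty_event_log <- data.frame(
  branch = character(0), time = numeric(0), kind = character(0),
  site = integer(0), detail = character(0), accepted = logical(0),
  rate = numeric(0), stringsAsFactors = FALSE
)

#' Waiting time to the next event
#'
#' @param total_rate sum of all event rates (>= 0).
#' @return an exponential draw with mean `1/total_rate`, or `Inf` when
#'   `total_rate` is 0 (no further event can occur).
#' @export
next_event_time <- function(total_rate) {
  if (!is.numeric(total_rate) || is.na(total_rate) || total_rate < 0) {
    stop("total rate must be nonnegative (internal consistency)",
         call. = FALSE)
  }
  if (total_rate == 0) return(Inf)
  stats::rexp(1, total_rate)
}

# select the initiating site proportionally to the cached site rates
select_site <- function(seq) {
  n <- length(seq$rates)
  if (n == 1L) return(1L)
  if (seq$uniform) {
    # all site rates equal: proportional sampling reduces to uniform
    return(min(n, floor(stats::runif(1) * n) + 1L))
  }
  cs <- cumsum(seq$rates)
  u <- stats::runif(1) * cs[n]
  min(findInterval(u, cs, left.open = TRUE) + 1L, n)
}

# per-binding event-initiation rates at a site (same arithmetic as
# compute_site_rate, itemized)
binding_rates <- function(seq, i) {
  vapply(seq$bindings[[i]], function(b) {
    p <- b$proc
    if (inherits(p, "gs_model")) {
      s <- p$alphabet$index[[seq$states[i]]]
      b$rm * -p$Q[s, s]
    } else if (inherits(p, "gs_deletion_process")) {
      r <- b$rm * p$rate
      if (p$mode == "fast_field") r <- r * fast_field_D(seq, p)
      r
    } else {
      b$rm * p$rate
    }
  }, numeric(1))
}

#' Select the next event
#'
#' Hierarchical sampling — site proportional to its cached event rate, a
#' binding within the site proportional to its rate, then the concrete
#' change (substitution target proportional to the rate-matrix row;
#' indel proposal constructed from the process) — so that every concrete
#' event has probability rate / total rate.
#'
#' @param seq a `gs_sequence` with positive total rate.
#' @return an object of class `gs_event`: `kind` (`"substitution"`,
#'   `"deletion"` or `"insertion"`), `site`, `rate` (the selected binding's
#'   rate), plus `target` (substitution), or `span` and `p_accept`
#'   (deletion), or `proc` and `length` (insertion).
#' @export
select_event <- function(seq) {
  if (seq$total_rate <= 0) {
    stop("select_event called with total rate 0", call. = FALSE)
  }
  i <- select_site(seq)
  br <- binding_rates(seq, i)
  cached <- seq$rates[i]
  if (abs(sum(br) - cached) > 1e-9 * max(1, cached)) {
    stop("rate audit: site ", i, " cached rate ", cached,
         " != sum of binding rates ", sum(br), call. = FALSE)
  }
  k <- if (length(br) == 1L) 1L else {
    cs <- cumsum(br)
    u <- stats::runif(1) * cs[length(cs)]
    min(findInterval(u, cs, left.open = TRUE) + 1L, length(br))
  }
  b <- seq$bindings[[i]][[k]]
  p <- b$proc
  if (inherits(p, "gs_model")) {
    s <- p$alphabet$index[[seq$states[i]]]
    w <- p$Q[s, ]
    w[s] <- 0
    cs <- cumsum(w)
    u <- stats::runif(1) * cs[length(cs)]
    j <- min(findInterval(u, cs, left.open = TRUE) + 1L, length(cs))
    structure(list(kind = "substitution", site = i, rate = br[k],
                   proc = p, target = p$alphabet$symbols[j]),
              class = "gs_event")
  } else if (inherits(p, "gs_deletion_process")) {
    span <- propose_deletion(seq, p, i)
    structure(list(kind = "deletion", site = i, rate = br[k], proc = p,
                   span = span,
                   p_accept = deletion_acceptance_probability(seq, span, p)),
              class = "gs_event")
  } else {
    len <- sample_indel_length(p$lengths)
    structure(list(kind = "insertion", site = i, rate = br[k], proc = p,
                   length = len,
                   p_accept = insertion_tolerance_at(seq, p, i)),
              class = "gs_event")
  }
}

# ephemeral homology-tracking environment for standalone branch runs;
# simulate_evolution() passes a shared one spanning the whole tree
new_sim_env <- function(seq) {
  e <- new.env(parent = emptyenv())
  e$columns <- seq$ids
  e$col_label <- seq$labels
  names(e$col_label) <- as.character(seq$ids)
  e$next_id <- seq$next_id
  e
}

#' Apply a selected event to the sequence
#'
#' Substitutions replace the site's state and update its cached rate in
#' place. Accepted deletions remove the span's sites; accepted insertions
#' splice the generated sites in immediately right of the initiating site,
#' assigning fresh site identities and new homology columns. Rejected indel
#' events mutate nothing (their time step was already consumed). Indel
#' events and property edits trigger a full rate recompute, which also
#' refreshes the fast-field maximum-tolerance cache.
#'
#' @param seq a `gs_sequence` (modified in place).
#' @param event a `gs_event` from [select_event()], with `accepted` set for
#'   indels.
#' @param sim homology-tracking environment (internal); `NULL` for a
#'   standalone sequence.
#' @return a list describing the applied alignment operation (`NULL` for
#'   substitutions and rejected events), invisibly.
#' @export
apply_event <- function(seq, event, sim = NULL) {
  if (is.null(sim)) sim <- new_sim_env(seq)
  op <- NULL
  if (event$kind == "substitution") {
    i <- event$site
    seq$states[i] <- event$target
    fp <- seq$fp
    new_r <- if (!is.null(fp) && isTRUE(fp$ok) && fp$version == seq$bver) {
      fp$rm[i] * fp$leave[[fp$index[[event$target]]]]
    } else {
      compute_site_rate(seq, i)
    }
    if (new_r != seq$rates[i]) {
      seq$total_rate <- seq$total_rate + (new_r - seq$rates[i])
      seq$rates[i] <- new_r
      seq$uniform <- FALSE
    }
  } else if (event$kind == "deletion") {
    if (isTRUE(event$accepted)) {
      idx <- event$span$from:event$span$to
      op <- list(type = "deletion", ids = seq$ids[idx])
      seq$states <- seq$states[-idx]
      seq$ids <- seq$ids[-idx]
      seq$labels <- seq$labels[-idx]
      seq$bindings <- seq$bindings[-idx]
      seq$bver <- seq$bver + 1L
      recompute_rates(seq)
    }
  } else if (event$kind == "insertion") {
    if (isTRUE(event$accepted)) {
      payload <- propose_insertion(seq, event$proc, event$site,
                                   length = event$length)
      at <- payload$at
      len <- length(payload$states)
      new_ids <- sim$next_id + seq_len(len) - 1L
      sim$next_id <- sim$next_id + len
      seq$next_id <- sim$next_id
      lab <- seq$labels[at]
      n <- length(seq$states)
      pre <- seq_len(at)
      post <- if (at < n) (at + 1L):n else integer(0)
      seq$states <- c(seq$states[pre], payload$states, seq$states[post])
      seq$ids <- c(seq$ids[pre], new_ids, seq$ids[post])
      seq$labels <- c(seq$labels[pre], rep(lab, len), seq$labels[post])
      seq$bindings <- c(seq$bindings[pre], payload$bindings,
                        seq$bindings[post])
      seq$bver <- seq$bver + 1L
      # new homology columns, immediately right of the initiating column
      anchor_id <- op_anchor <- seq$ids[at]
      pos <- match(anchor_id, sim$columns)
      sim$columns <- append(sim$columns, new_ids, after = pos)
      sim$col_label[as.character(new_ids)] <- lab
      recompute_rates(seq)
      op <- list(type = "insertion", after_id = op_anchor, ids = new_ids,
                 states = payload$states)
    }
  }
  invisible(op)
}

#' Evolve a sequence along one branch
#'
#' Runs the Gillespie loop: draw the waiting time, stop if it overruns the
#' branch, otherwise select an event, accept/reject it if it is an indel,
#' apply it, and repeat. Cached rates are fully recomputed from the bindings
#' at the start of the branch and audited against an independent recompute
#' every `audit_interval` events (relative tolerance 1e-9; a mismatch
#' aborts). Deterministic given the RNG state.
#'
#' @param seq a `gs_sequence` (modified in place; clone first if the parent
#'   state must be kept).
#' @param branch_length nonnegative branch length in expected substitutions
#'   per site.
#' @param sim internal homology-tracking environment (`NULL` for standalone
#'   use).
#' @param branch_label label recorded in the event log.
#' @param audit_interval events between full rate recomputations.
#' @param log_events set to `FALSE` to skip building the per-event log
#'   (faster for large replicate studies that only need the end state);
#'   `events` is then an empty data frame and `n_events` carries the count.
#' @return an object of class `gs_branch_result`: `seq` (the evolved
#'   sequence), `events` (a data frame: branch, time, kind, site, detail,
#'   accepted, rate), and `ops` (the list of applied alignment operations).
#' @examples
#' set.seed(1)
#' s <- root_sequence(20, k80_model(2))
#' res <- evolve_branch(s, 0.5)
#' nrow(res$events)
#' @export
evolve_branch <- function(seq, branch_length, sim = NULL,
                          branch_label = "branch", audit_interval = 1000L,
                          log_events = TRUE) {
  stopifnot(inherits(seq, "gs_sequence"))
  if (!is.numeric(branch_length) || branch_length < 0) {
    stop("branch length must be >= 0", call. = FALSE)
  }
  if (is.null(sim)) sim <- new_sim_env(seq)
  recompute_rates(seq)

  t <- 0
  n_ev <- 0L
  cap <- 256L
  ev_time <- numeric(cap); ev_kind <- character(cap); ev_site <- integer(cap)
  ev_detail <- character(cap); ev_acc <- logical(cap); ev_rate <- numeric(cap)
  ops <- list()

  repeat {
    tot <- seq$total_rate
    if (tot <= 0) break
    dt <- stats::rexp(1, tot)
    if (t + dt > branch_length) break
    t <- t + dt
    ev <- select_event(seq)

    if (ev$kind == "substitution") {
      detail <- if (log_events) paste0(seq$states[ev$site], "->", ev$target)
      accepted <- TRUE
    } else {
      ev$accepted <- accept_or_reject(ev$p_accept)
      accepted <- ev$accepted
      detail <- if (!log_events) NULL else if (ev$kind == "deletion") {
        sprintf("del %d..%d (len %d%s, p=%.4g)", ev$span$from, ev$span$to,
                ev$span$proposed_length,
                if (ev$span$truncated) ", truncated" else "", ev$p_accept)
      } else {
        sprintf("ins len %d after %d (p=%.4g)", ev$length, ev$site,
                ev$p_accept)
      }
    }
    site_at_event <- ev$site
    op <- apply_event(seq, ev, sim)
    if (!is.null(op)) ops[[length(ops) + 1L]] <- op

    n_ev <- n_ev + 1L
    if (log_events) {
      if (n_ev > cap) {  # grow log buffers geometrically
        cap <- cap * 2L
        length(ev_time) <- cap; length(ev_kind) <- cap
        length(ev_site) <- cap; length(ev_detail) <- cap
        length(ev_acc) <- cap; length(ev_rate) <- cap
      }
      ev_time[n_ev] <- t; ev_kind[n_ev] <- ev$kind
      ev_site[n_ev] <- site_at_event; ev_detail[n_ev] <- detail
      ev_acc[n_ev] <- accepted; ev_rate[n_ev] <- ev$rate
    }

    if (n_ev %% audit_interval == 0L) {
      cached <- seq$total_rate
      recompute_rates(seq)
      if (abs(cached - seq$total_rate) >
          1e-9 * max(1, abs(seq$total_rate))) {
        stop("rate audit failed on branch '", branch_label, "': cached ",
             cached, " vs recomputed ", seq$total_rate, call. = FALSE)
      }
    }
  }

  events <- if (!log_events || n_ev == 0L) {
    empty_event_log
  } else {
    keep <- seq_len(n_ev)
    data.frame(
      branch = rep(branch_label, n_ev), time = ev_time[keep],
      kind = ev_kind[keep], site = ev_site[keep], detail = ev_detail[keep],
      accepted = ev_acc[keep], rate = ev_rate[keep],
      stringsAsFactors = FALSE
    )
  }
  structure(list(seq = seq, events = events, ops = ops, n_events = n_ev),
            class = "gs_branch_result")
}
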