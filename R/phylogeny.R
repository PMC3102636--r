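# ---- tree traversal and node hooks -------------------------------------------

#' Read a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the input for
#' simulation: branch lengths present and nonnegative, tip labels unique.
#' Unlabelled internal nodes are assigned labels `Node1`, `Node2`, ... so
#' hooks and per-branch random substreams can address them.
#'
#' @param x Newick text, or the path of a file containing one tree.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    stop("could not parse Newick input: ", substr(txt, 1, 60), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label))) {
    auto <- paste0("Node", seq_len(tree$Nnode))
    if (is.null(tree$node.label)) {
      tree$node.label <- auto
    } else {
      blank <- !nzchar(tree$node.label)
      tree$node.label[blank] <- auto[blank]
    }
  }
  tree
}

#' Define a node hook
#'
#' Node hooks implement time-non-homogeneous evolution (heterotachy,
#' changing indel constraints): a hook runs at its target node *before* the
#' child branches are simulated, so the change is inherited by the whole
#' subtree. Hooks may only alter site properties — through
#' [set_site_property()] or [attach_process()] — never states or sequence
#' length; this is enforced and a violating hook is reported by name.
#'
#' @param target a node label, or a predicate `function(label)` selecting
#'   nodes.
#' @param action `function(seq)` mutating the node's sequence in place.
#' @param label hook name used in error messages.
#' @return an object of class `gs_hook`.
#' @export
node_hook <- function(target, action, label = "hook") {
  stopifnot(is.function(action))
  structure(list(target = target, action = action, label = label),
            class = "gs_hook")
}

hook_matches <- function(hook, node_label) {
  if (is.function(hook$target)) {
    isTRUE(hook$target(node_label))
  } else {
    node_label %in% hook$target
  }
}

run_hooks <- function(hooks, node_label, seq) {
  for (h in hooks) {
    if (!hook_matches(h, node_label)) next
    before_states <- seq$states
    h$action(seq)
    if (length(seq$states) != length(before_states) ||
        !identical(seq$states, before_states)) {
      stop("node hook '", h$label, "' at node '", node_label,
           "' changed states or sequence length; hooks may only alter ",
           "site properties", call. = FALSE)
    }
  }
  invisible(seq)
}

# deterministic per-branch substream seed from (seed, label); kept < 2^31
# and computed in exact double arithmetic
substream_seed <- function(seed, label) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  ((seed %% 94906265) * 22695477 + h + 1) %% m
}

#' Simulate sequence evolution along a phylogeny
#'
#' Pre-order traversal from the root: at each node, hooks targeting that
#' node run first; each child branch then evolves an independent copy of the
#' node's sequence with [evolve_branch()]. Indel events are threaded into a
#' global homology-column structure, from which the true multiple alignment
#' can be built with [build_true_alignment()].
#'
#' When `seed` is given, every branch (and nothing else) consumes a private
#' random substream derived deterministically from `(seed, child label)`, so
#' runs are exactly reproducible and adding outputs never perturbs the
#' simulation stream.
#'
#' @param tree an [ape::phylo] tree (see [read_newick()]) with branch
#'   lengths in expected substitutions per site.
#' @param root a `gs_sequence` used as the root state.
#' @param hooks list of [node_hook()]s.
#' @param seed optional integer seed.
#' @return an object of class `gs_simulation` with elements `tree`, `nodes`
#'   (per node label: list with `ids`, `states`, `labels`), `tips` (tip
#'   labels), `events` (combined event-log data frame), `ops` (per-branch
#'   alignment operations, in traversal order), `columns` (global homology
#'   column ids), `column_label` (per-column partition annotation) and
#'   `root_label`.
#' @export
simulate_evolution <- function(tree, root, hooks = list(), seed = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"), inherits(root, "gs_sequence"))
  if (inherits(hooks, "gs_hook")) hooks <- list(hooks)
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) {
    tree$node.label <- paste0("Node", seq_len(tree$Nnode))
  }
  node_label <- c(tree$tip.label, tree$node.label)
  root_node <- ntip + 1L

  sim <- new.env(parent = emptyenv())
  sim$columns <- root$ids
  sim$col_label <- stats::setNames(root$labels, as.character(root$ids))
  sim$next_id <- root$next_id

  nodes <- list()
  events <- list()
  ops <- list()
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  recurse <- function(node, seq) {
    lab <- node_label[node]
    run_hooks(hooks, lab, seq)
    nodes[[lab]] <<- list(ids = seq$ids, states = seq$states,
                          labels = seq$labels)
    for (e in children_of[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      child_lab <- node_label[child]
      child_seq <- clone_sequence(seq)
      child_seq$next_id <- sim$next_id
      if (!is.null(seed)) set.seed(substream_seed(seed, child_lab))
      br <- evolve_branch(child_seq, tree$edge.length[e], sim = sim,
                          branch_label = child_lab)
      events[[length(events) + 1L]] <<- br$events
      ops[[child_lab]] <<- br$ops
      recurse(child, child_seq)
    }
  }
  recurse(root_node, root)

  structure(
    list(tree = tree, nodes = nodes, tips = tree$tip.label,
         events = do.call(rbind, events) %||% empty_event_log,
         ops = ops, columns = sim$columns,
         column_label = sim$col_label, root_label = node_label[root_node]),
    class = "gs_simulation"
  )
}

#' @export
print.gs_simulation <- function(x, ...) {
  cat("<simulation: ", length(x$tips), " tips, ",
      length(x$columns), " homology columns, ",
      nrow(x$events), " events>\n", sep = "")
  invisible(x)
}
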