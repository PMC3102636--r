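# ---- the true multiple alignment ---------------------------------------------
#
# Every site carries a unique identity from its creation (root site or
# insertion event) to its deletion. The global column structure is the
# ordered list of all identities ever created, with insertion columns
# spliced immediately right of the initiating site's column. A node's
# alignment row places its tokens at the columns of its site identities and
# gaps everywhere else, so homology in the output alignment is the true
# homology of the simulation — the ground truth against which aligners can
# be benchmarked.

#' Build the true multiple alignment of a simulation
#'
#' @param result a `gs_simulation` from [simulate_evolution()].
#' @param include_internal also emit rows for internal nodes (including the
#'   root).
#' @param drop_all_gap_columns drop columns that are gaps in every emitted
#'   row (e.g. an insertion on an internal branch subsequently deleted in
#'   all surviving lineages leaves no evidence at the tips).
#' @return an object of class `gs_alignment`: `tokens` (rows x columns
#'   character matrix of tokens, `NA` for gaps), `sequences` (named vector
#'   of gapped row strings; gap runs are `-` repeated to the column's token
#'   width), `annotation` (data frame with 1-based `column` and `partition`
#'   label) and `column_ids` (site identities, for replay checks).
#' @export
build_true_alignment <- function(result, include_internal = FALSE,
                                 drop_all_gap_columns = TRUE) {
  stopifnot(inherits(result, "gs_simulation"))
  rows <- if (include_internal) names(result$nodes) else result$tips
  cols <- result$columns
  k <- length(cols)
  tok <- matrix(NA_character_, nrow = length(rows), ncol = k,
                dimnames = list(rows, NULL))
  for (r in rows) {
    node <- result$nodes[[r]]
    pos <- match(node$ids, cols)
    tok[r, pos] <- node$states
  }
  keep <- rep(TRUE, k)
  if (drop_all_gap_columns && k > 0L) {
    keep <- colSums(!is.na(tok)) > 0L
    tok <- tok[, keep, drop = FALSE]
    cols <- cols[keep]
  }
  width <- apply(tok, 2, function(col) {
    w <- nchar(col[!is.na(col)])
    if (length(w)) max(w) else 1L
  })
  if (ncol(tok) == 0L) width <- integer(0)
  seqs <- apply(tok, 1, function(row) {
    row[is.na(row)] <- strrep("-", width)[is.na(row)]
    # pad narrow tokens in mixed-width columns (does not occur with the
    # shipped models, which never mix token widths in one column)
    paste(row, collapse = "")
  })
  if (length(rows) == 0L) seqs <- character(0)
  annotation <- data.frame(
    column = seq_along(cols),
    partition = unname(result$column_label[as.character(cols)]),
    stringsAsFactors = FALSE
  )
  structure(list(tokens = tok, sequences = stats::setNames(seqs, rows),
                 annotation = annotation, column_ids = cols),
            class = "gs_alignment")
}

#' @export
print.gs_alignment <- function(x, ...) {
  cat("<true alignment: ", nrow(x$tokens), " rows x ", ncol(x$tokens),
      " columns>\n", sep = "")
  invisible(x)
}

#' Remove gaps from an alignment row
#'
#' @param alignment a `gs_alignment`.
#' @param row row (node) label.
#' @return character vector of the row's tokens with gaps removed; equals
#'   the node's sequence exactly.
#' @export
degap_row <- function(alignment, row) {
  tk <- alignment$tokens[row, ]
  unname(tk[!is.na(tk)])
}

#' Replay logged alignment operations
#'
#' Reconstructs every node's site-identity vector, and the global column
#' structure, purely from the root identities and the per-branch logged
#' alignment operations, then compares them with the structures built
#' online during the simulation. Used to verify that the event log fully
#' determines the true alignment.
#'
#' @param result a `gs_simulation`.
#' @return `TRUE` (invisibly) if the replay matches exactly; otherwise an
#'   error describing the first mismatch.
#' @export
replay_alignment_ops <- function(result) {
  tree <- result$tree
  ntip <- length(tree$tip.label)
  node_label <- c(tree$tip.label, tree$node.label)
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root_ids <- result$nodes[[result$root_label]]$ids
  columns <- root_ids

  apply_ops <- function(ids, ops) {
    for (op in ops) {
      if (op$type == "deletion") {
        ids <- ids[!(ids %in% op$ids)]
      } else {
        pos <- match(op$after_id, ids)
        if (is.na(pos)) {
          stop("replay: insertion anchor id ", op$after_id,
               " absent from the branch sequence", call. = FALSE)
        }
        ids <- append(ids, op$ids, after = pos)
        cpos <- match(op$after_id, columns)
        columns <<- append(columns, op$ids, after = cpos)
      }
    }
    ids
  }

  recurse <- function(node, ids) {
    for (e in children_of[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      lab <- node_label[child]
      child_ids <- apply_ops(ids, result$ops[[lab]])
      stored <- result$nodes[[lab]]$ids
      if (!identical(as.integer(child_ids), as.integer(stored))) {
        stop("replay mismatch at node '", lab, "'", call. = FALSE)
      }
      recurse(child, child_ids)
    }
  }
  recurse(ntip + 1L, root_ids)
  if (!identical(as.integer(columns), as.integer(result$columns))) {
    stop("replay mismatch in the global column structure", call. = FALSE)
  }
  invisible(TRUE)
}
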