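# ---- end-to-end run -----------------------------------------------------------

# build the root sequence described by a validated config; consumes the
# current RNG stream (the caller seeds it)
build_root_from_config <- function(cfg, procs) {
  if (!is.null(cfg$root$fasta)) {
    fa <- seqinr::read.fasta(cfg$root$fasta, as.string = TRUE,
                             forceDNAtolower = FALSE)
    cfg$root$tokens <- split_fasta_root(cfg, procs,
                                        toupper(as.character(fa[[1]])))
  }
  parts <- list()
  for (i in seq_along(cfg$partitions)) {
    p <- cfg$partitions[[i]]
    n_sites <- p$to - p$from + 1L
    sub <- NULL
    for (pn in p$processes %||% character(0)) {
      if (inherits(procs[[pn]], "gs_model")) { sub <- procs[[pn]]; break }
    }
    rate_model <- if (!is.null(p$site_rates)) {
      build_rate_model(p$site_rates, "site_rates")
    }
    dt <- p$deletion_tolerance %||% 1
    it <- p$insertion_tolerance %||% 1
    lab <- p$name %||% paste0("partition", i)
    toks <- if (!is.null(cfg$root$tokens)) {
      tk <- cfg$root$tokens
      if (is.list(tk) || length(tk) > 1L) tk[[i]] else tk
    }
    part <- if (!is.null(toks)) {
      root_sequence_from_string(toks, model = sub, rate_model = rate_model,
                                deletion_tolerance = dt,
                                insertion_tolerance = it, label = lab)
    } else {
      if (is.null(sub)) {
        stop("partition '", lab, "' has no substitution process; fixed ",
             "motifs need explicit root tokens", call. = FALSE)
      }
      root_sequence(n_sites, sub, rate_model = rate_model,
                    deletion_tolerance = dt, insertion_tolerance = it,
                    label = lab)
    }
    if (length(part$states) != n_sites) {
      stop("partition '", lab, "' spans ", n_sites, " sites but its root ",
           "tokens give ", length(part$states), call. = FALSE)
    }
    # attach the remaining processes (extra substitution models, indels)
    first_sub_seen <- FALSE
    for (pn in p$processes %||% character(0)) {
      pr <- procs[[pn]]
      if (inherits(pr, "gs_model")) {
        if (!first_sub_seen && identical(pr$pid, sub$pid)) {
          first_sub_seen <- TRUE
          next
        }
      }
      attach_process(part, 1L, length(part$states), pr,
                     deletion_tolerance = dt, insertion_tolerance = it)
    }
    parts[[i]] <- part
  }
  concat_sequences(parts)
}

# split a single root string read from FASTA into per-partition token
# vectors, honouring each partition's token width
split_fasta_root <- function(cfg, procs, whole) {
  out <- list()
  off <- 0L
  for (i in seq_along(cfg$partitions)) {
    p <- cfg$partitions[[i]]
    n_sites <- p$to - p$from + 1L
    sub <- NULL
    for (pn in p$processes %||% character(0)) {
      if (inherits(procs[[pn]], "gs_model")) { sub <- procs[[pn]]; break }
    }
    w <- if (is.null(sub)) 1L else alphabet_width(sub$alphabet)
    chars <- n_sites * w
    out[[i]] <- substr(whole, off + 1L, off + chars)
    off <- off + chars
  }
  out
}

# turn declarative config hooks into gs_hook objects
build_hooks_from_config <- function(cfg, procs) {
  lapply(seq_along(cfg$hooks %||% list()), function(i) {
    h <- cfg$hooks[[i]]
    proc <- if (!is.null(h$process)) procs[[h$process]]
    node_hook(h$node, function(seq) {
      n <- length(seq$states)
      idx <- max(1L, h$from %||% 1L):min(n, h$to %||% n)
      apply_one <- function(pr) {
        if (!is.null(h$scale_rate_multiplier)) {
          for (j in idx) {
            cur <- tryCatch(
              get_site_property(seq, j, pr, "rate_multiplier"),
              error = function(e) NULL)
            if (!is.null(cur)) {
              set_site_property(seq, j, pr, "rate_multiplier",
                                cur * h$scale_rate_multiplier)
            }
          }
        }
        for (key in c("rate_multiplier", "deletion_tolerance",
                      "insertion_tolerance")) {
          if (!is.null(h[[key]])) {
            for (j in idx) {
              ok <- tryCatch({
                set_site_property(seq, j, pr, key, h[[key]]); TRUE
              }, error = function(e) FALSE)
            }
          }
        }
      }
      targets <- if (!is.null(proc)) list(proc) else {
        unique(unlist(lapply(seq$bindings[idx],
                             function(bl) lapply(bl, `[[`, "proc")),
               recursive = FALSE))
      }
      for (pr in targets) apply_one(pr)
    }, label = paste0("config-hook-", i))
  })
}

#' Run a configured simulation and write its outputs
#'
#' Executes the full pipeline: parse the tree, build the root sequence
#' (seeded substream), simulate along the tree, build the true alignment,
#' and write `<prefix>_tips.fasta` (ungapped tip sequences),
#' `<prefix>_alignment.fasta` (gapped true alignment),
#' `<prefix>_tracks.tsv` (per-column partition annotation),
#' `<prefix>_events.tsv` (event log) and `<prefix>_manifest.yaml` (seed,
#' package version, config echo). Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config a config path or list (see [load_config()]).
#' @param out_prefix output path prefix.
#' @param seed optional seed overriding the config's.
#' @return invisibly, a list with the simulation result, the alignment and
#'   the written file paths.
#' @export
run_simulation <- function(config, out_prefix, seed = NULL) {
  cfg <- if (inherits(config, "gs_config")) config else load_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  procs <- config_processes(cfg)
  tree <- read_newick(cfg$tree)
  set.seed(substream_seed(seed, "__root__"))
  root <- build_root_from_config(cfg, procs)
  hooks <- build_hooks_from_config(cfg, procs)
  result <- simulate_evolution(tree, root, hooks = hooks, seed = seed)

  include_internal <- isTRUE(cfg$outputs$include_internal)
  drop_gaps <- cfg$outputs$drop_all_gap_columns %||% TRUE
  aln <- build_true_alignment(result, include_internal = include_internal,
                              drop_all_gap_columns = drop_gaps)

  tips <- vapply(result$tips, function(tp) {
    paste(result$nodes[[tp]]$states, collapse = "")
  }, character(1))

  paths <- paste0(out_prefix, c("_tips.fasta", "_alignment.fasta",
                                "_tracks.tsv", "_events.tsv",
                                "_manifest.yaml"))
  names(paths) <- c("tips", "alignment", "tracks", "events", "manifest")
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)

  write_fasta(tips, paths[["tips"]])
  write_fasta(aln$sequences, paths[["alignment"]])
  utils::write.table(aln$annotation, paths[["tracks"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$events, paths[["events"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = seed,
    package = "gillesim",
    version = as.character(utils::packageVersion("gillesim")),
    n_tips = length(result$tips),
    n_events = nrow(result$events),
    alignment_columns = ncol(aln$tokens),
    config = unclass(cfg)
  )
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(list(result = result, alignment = aln, paths = paths))
}
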