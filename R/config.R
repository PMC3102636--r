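# ---- run configuration --------------------------------------------------------
#
# A run is described by a YAML document (or the equivalent R list):
#
#   seed: 1
#   tree: "(A:0.2,B:0.2);"          # Newick text or a file path
#   root:
#     length: 100                    # equilibrium root, or
#     tokens: [ "ACGT...", ... ]     # explicit tokens, one entry/partition
#   processes:
#     sub: {type: k80, kappa: 2}
#     del: {type: deletion, rate: 0.1, mode: plain_field,
#           lengths: {kind: fixed, size: 1}}
#   partitions:
#     - {name: all, from: 1, to: 100, processes: [sub, del],
#        site_rates: {kind: discrete_gamma, alpha: 0.5, categories: 4},
#        deletion_tolerance: 1, insertion_tolerance: 1}
#   hooks:                           # declarative property-set hooks
#     - {node: Node2, process: sub, from: 1, to: 50,
#        scale_rate_multiplier: 0.5}
#   outputs: {include_internal: false, drop_all_gap_columns: true}
#
# Partition ranges are in sites (a site is one token: a codon for codon
# models); a partition with no substitution process is a fixed motif.
# Deletions are free to cross partition boundaries.

#' Load and validate a run configuration
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated config (class `gs_config`), with all process
#'   cross-references resolved; schema violations raise errors naming the
#'   offending key.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)

  fail <- function(key, msg) {
    stop("config error at '", key, "': ", msg, call. = FALSE)
  }
  if (is.null(cfg$tree)) fail("tree", "missing")
  if (is.null(cfg$root)) fail("root", "missing")
  if (is.null(cfg$root$length) && is.null(cfg$root$tokens) &&
      is.null(cfg$root$fasta)) {
    fail("root", "need one of length / tokens / fasta")
  }
  seed <- cfg$seed %||% 0L
  if (!is.numeric(seed) || seed < 0 || seed != round(seed)) {
    fail("seed", "must be a nonnegative integer")
  }
  if (!is.list(cfg$processes) || !length(cfg$processes)) {
    fail("processes", "at least one process must be defined")
  }
  procs <- config_processes(cfg)
  if (is.null(cfg$partitions) || !length(cfg$partitions)) {
    fail("partitions", "at least one partition must be defined")
  }
  for (i in seq_along(cfg$partitions)) {
    p <- cfg$partitions[[i]]
    key <- paste0("partitions[", i, "]")
    if (is.null(p$from) || is.null(p$to) || p$from < 1 || p$to < p$from) {
      fail(key, "needs 1-based 'from' <= 'to'")
    }
    for (pn in p$processes %||% character(0)) {
      if (!pn %in% names(procs)) {
        fail(paste0(key, ".processes"), paste0("undefined process '", pn, "'"))
      }
    }
    for (tol in c("deletion_tolerance", "insertion_tolerance")) {
      v <- p[[tol]]
      if (!is.null(v) && (any(v < 0) || any(v > 1))) {
        fail(paste0(key, ".", tol), "must be in [0, 1]")
      }
    }
    if (!is.null(p$site_rates)) {
      build_rate_model(p$site_rates, paste0(key, ".site_rates"))
    }
    sub_names <- Filter(function(pn) inherits(procs[[pn]], "gs_model"),
                        p$processes %||% character(0))
    if (length(sub_names) > 1L) {
      abs <- lapply(sub_names, function(pn) procs[[pn]]$alphabet$symbols)
      if (!all(vapply(abs, identical, logical(1), abs[[1]]))) {
        fail(paste0(key, ".processes"),
             "substitution processes on one partition must share an alphabet")
      }
    }
  }
  for (i in seq_along(cfg$hooks %||% list())) {
    h <- cfg$hooks[[i]]
    key <- paste0("hooks[", i, "]")
    if (is.null(h$node)) fail(key, "needs a 'node' label")
    if (!is.null(h$process) && !h$process %in% names(procs)) {
      fail(paste0(key, ".process"), paste0("undefined process '", h$process, "'"))
    }
    known <- c("node", "process", "from", "to", "rate_multiplier",
               "scale_rate_multiplier", "deletion_tolerance",
               "insertion_tolerance")
    extra <- setdiff(names(h), known)
    if (length(extra)) fail(key, paste0("unknown keys: ",
                                        paste(extra, collapse = ", ")))
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = c("gs_config", "list"))
}

#' @rdname load_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# build all process objects from the config, resolving insertion templates
config_processes <- function(cfg) {
  procs <- list()
  for (nm in names(cfg$processes)) {
    procs[[nm]] <- build_process(cfg$processes[[nm]],
                                 paste0("processes.", nm))
  }
  resolve_insertions(procs, cfg)
}

# build one process object from its config entry
build_process <- function(spec, key) {
  fail <- function(msg) stop("config error at '", key, "': ", msg,
                             call. = FALSE)
  if (is.null(spec$type)) fail("missing 'type'")
  switch(spec$type,
    k80 = k80_model(spec$kappa %||% fail("k80 needs 'kappa'")),
    gtr = gtr_model(spec$exchangeabilities, spec$frequencies),
    unrest = unrest_model(unlist(spec$rates)),
    gy94 = gy94_model(spec$kappa, spec$omega,
                      codon_freqs = spec$codon_freqs %||% "equal"),
    empirical_aa = empirical_aa_model(spec$source),
    general = {
      ab <- make_alphabet(unlist(spec$alphabet))
      R <- matrix(unlist(spec$rates), length(ab$symbols), byrow = TRUE)
      general_model(ab, R, normalize = spec$normalize %||% TRUE,
                    label = spec$label %||% "general")
    },
    deletion = deletion_process(
      spec$rate, build_lengths(spec$lengths, key),
      mode = spec$mode %||% "plain_field",
      label = spec$label %||% "deletion"),
    insertion = {
      tpl <- list()
      if (!is.null(spec$template)) tpl$model_name <- spec$template
      structure(list(spec = spec, key = key, template_name = spec$template),
                class = "gs_insertion_stub")
    },
    fail(paste0("unknown process type '", spec$type, "'"))
  )
}

# insertion processes reference another process as their template, so they
# are resolved after all substitution processes are built
resolve_insertions <- function(procs, cfg) {
  for (nm in names(procs)) {
    p <- procs[[nm]]
    if (inherits(p, "gs_insertion_stub")) {
      spec <- p$spec
      tpl_name <- p$template_name
      if (is.null(tpl_name) || !inherits(procs[[tpl_name]], "gs_model")) {
        stop("config error at '", p$key,
             "': insertion needs 'template' naming a substitution process",
             call. = FALSE)
      }
      tpl <- list(model = procs[[tpl_name]])
      if (!is.null(spec$site_rates)) {
        tpl$rate_model <- build_rate_model(spec$site_rates,
                                           paste0(p$key, ".site_rates"))
      }
      tpl$deletion_tolerance <- spec$deletion_tolerance %||% 1
      tpl$insertion_tolerance <- spec$insertion_tolerance %||% 1
      procs[[nm]] <- insertion_process(
        spec$rate, build_lengths(spec$lengths, p$key), template = tpl,
        label = spec$label %||% "insertion")
    }
  }
  procs
}

build_lengths <- function(spec, key) {
  if (is.null(spec)) return(fixed_length(1L))
  switch(spec$kind %||% "fixed",
    fixed = fixed_length(spec$size %||% 1L),
    geometric = geometric_length(spec$p),
    poisson_shifted = poisson_length(spec$lambda),
    user_table = table_length(unlist(spec$lengths), unlist(spec$probs)),
    stop("config error at '", key, ".lengths': unknown kind '", spec$kind,
         "'", call. = FALSE)
  )
}

build_rate_model <- function(spec, key) {
  kind <- spec$kind %||% "constant"
  tryCatch(
    site_rate_model(kind, alpha = spec$alpha,
                    n_categories = spec$categories %||% 4L,
                    p_inv = spec$p_inv %||% 0),
    error = function(e) stop("config error at '", key, "': ",
                             conditionMessage(e), call. = FALSE)
  )
}
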