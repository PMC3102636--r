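# ---- synthetic fixtures for tests and demos ------------------------------------

#' Generate a deterministic synthetic fixture
#'
#' Builds small, fully self-contained simulation inputs (a Newick tree plus
#' a run config) for tests and demonstrations. Kinds:
#' \describe{
#'   \item{random_tree}{a random rooted tree with `n` tips (branch lengths
#'     uniform on `[0.05, 0.3]`) over a single JC-like nucleotide partition
#'     with optional indel processes.}
#'   \item{coding_region}{a miniature genomic region: K80 noncoding flanks
#'     and intron, a fixed ATG start codon and GT/AG splice motifs, two GY94
#'     exons, and a stop codon evolving by a special unnormalized 3-state
#'     substitution process over TAA/TAG/TGA.}
#'   \item{domain_protein}{a protein with two domains under different
#'     empirical amino-acid models (WAG and LG) and different deletion
#'     tolerances — a deletion-intolerant core and a tolerant linker.}
#' }
#'
#' @param kind fixture kind.
#' @param params named list of overrides (e.g. `n`, `length`, `indels`,
#'   `n_codons`, `deletion_rate`).
#' @param seed integer seed; the same seed always returns the identical
#'   fixture.
#' @return list with `tree` (Newick string) and `config` (a list accepted by
#'   [load_config()]).
#' @export
generate_fixture <- function(kind = c("random_tree", "coding_region",
                                      "domain_protein"),
                             params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    random_tree = fixture_random_tree(params, seed),
    coding_region = fixture_coding_region(params, seed),
    domain_protein = fixture_domain_protein(params, seed)
  )
}

random_newick <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE,
                   br = function(k) stats::runif(k, 0.05, 0.3))
  ape::write.tree(tr)
}

fixture_random_tree <- function(params, seed) {
  n <- params$n %||% 5L
  len <- params$length %||% 100L
  indels <- params$indels %||% TRUE
  tree <- random_newick(n)
  processes <- list(sub = list(type = "k80", kappa = 2))
  part_procs <- "sub"
  if (indels) {
    processes$del <- list(type = "deletion",
                          rate = params$deletion_rate %||% 0.05,
                          mode = "plain_field",
                          lengths = list(kind = "user_table",
                                         lengths = c(1L, 2L, 3L),
                                         probs = c(0.6, 0.3, 0.1)))
    processes$ins <- list(type = "insertion",
                          rate = params$insertion_rate %||% 0.03,
                          template = "sub",
                          lengths = list(kind = "geometric", p = 0.5))
    part_procs <- c("sub", "del", "ins")
  }
  config <- list(
    seed = seed, tree = tree, root = list(length = len),
    processes = processes,
    partitions = list(list(name = "all", from = 1L, to = len,
                           processes = part_procs,
                           deletion_tolerance = params$deletion_tolerance %||% 0.8))
  )
  list(tree = tree, config = config)
}

fixture_coding_region <- function(params, seed) {
  n_codons <- params$n_codons %||% 6L
  flank <- params$flank %||% 15L
  intron <- params$intron %||% 12L
  tree <- params$tree %||%
    "(((human:0.1,chimp:0.12):0.08,macaque:0.2):0.1,(mouse:0.3,rat:0.28):0.15);"

  gy <- gy94_model(2, params$omega %||% 0.2)
  exon1 <- paste(sample(gy$alphabet$symbols, n_codons, replace = TRUE,
                        prob = gy$pi), collapse = "")
  exon2 <- paste(sample(gy$alphabet$symbols, n_codons, replace = TRUE,
                        prob = gy$pi), collapse = "")
  flank5 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  intron_seq <- paste(sample(c("A", "C", "G", "T"), intron, TRUE),
                      collapse = "")
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)

  # site layout (1 site = 1 token: codons are single sites, the fixed
  # nucleotide motifs ATG / GT / AG are one site per character, and the stop
  # codon is a single triplet site under its own 3-state process)
  lens <- c(flank, 3L, n_codons, 2L, intron, 2L, n_codons, 1L, flank)
  to <- cumsum(lens)
  from <- to - lens + 1L

  # the stop codon evolves by a slow special process on the three
  # functionally equivalent stops; unnormalized so its rate is absolute
  stop_rates <- list(c(0, 0.1, 0.1), c(0.1, 0, 0.1), c(0.1, 0.1, 0))

  config <- list(
    seed = seed, tree = tree,
    root = list(tokens = list(flank5, "ATG", exon1, "GT", intron_seq, "AG",
                              exon2, stop_codon, flank3)),
    processes = list(
      k80 = list(type = "k80", kappa = 2),
      gy94 = list(type = "gy94", kappa = 2, omega = params$omega %||% 0.2),
      stopproc = list(type = "general",
                      alphabet = c("TAA", "TAG", "TGA"),
                      rates = stop_rates, normalize = FALSE,
                      label = "stop-codon"),
      del = list(type = "deletion", rate = params$deletion_rate %||% 0.02,
                 mode = "plain_field",
                 lengths = list(kind = "geometric", p = 0.5))
    ),
    partitions = list(
      list(name = "flank5", from = from[1], to = to[1],
           processes = c("k80", "del"), deletion_tolerance = 1),
      list(name = "start_codon", from = from[2], to = to[2],
           processes = "del", deletion_tolerance = 0),
      list(name = "exon1", from = from[3], to = to[3],
           processes = c("gy94", "del"), deletion_tolerance = 0.1),
      list(name = "splice_donor", from = from[4], to = to[4],
           processes = "del", deletion_tolerance = 0),
      list(name = "intron", from = from[5], to = to[5],
           processes = c("k80", "del"), deletion_tolerance = 1),
      list(name = "splice_acceptor", from = from[6], to = to[6],
           processes = "del", deletion_tolerance = 0),
      list(name = "exon2", from = from[7], to = to[7],
           processes = c("gy94", "del"), deletion_tolerance = 0.1),
      list(name = "stop_codon", from = from[8], to = to[8],
           processes = c("stopproc", "del"), deletion_tolerance = 0),
      list(name = "flank3", from = from[9], to = to[9],
           processes = c("k80", "del"), deletion_tolerance = 1)
    )
  )
  list(tree = tree, config = config)
}

fixture_domain_protein <- function(params, seed) {
  n_core <- params$n_core %||% 40L
  n_linker <- params$n_linker %||% 20L
  tree <- random_newick(params$n %||% 5L)
  config <- list(
    seed = seed, tree = tree,
    root = list(length = n_core + n_linker),
    processes = list(
      wag = list(type = "empirical_aa", source = "WAG"),
      lg = list(type = "empirical_aa", source = "LG"),
      del = list(type = "deletion", rate = params$deletion_rate %||% 0.05,
                 mode = "fast_field",
                 lengths = list(kind = "geometric", p = 0.6)),
      ins = list(type = "insertion", rate = 0.02, template = "lg",
                 lengths = list(kind = "geometric", p = 0.6))
    ),
    partitions = list(
      list(name = "core", from = 1L, to = n_core,
           processes = c("wag", "del"),
           site_rates = list(kind = "discrete_gamma", alpha = 0.7,
                             categories = 4L),
           deletion_tolerance = 0.05),
      list(name = "linker", from = n_core + 1L, to = n_core + n_linker,
           processes = c("lg", "del", "ins"),
           deletion_tolerance = 0.9)
    )
  )
  list(tree = tree, config = config)
}
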