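# tree recursion, node hooks, and true-alignment assembly

test_that("newick parsing validates structure and labels internal nodes", {
  tr <- read_newick("(A:0.1,B:0.2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))

  tr2 <- read_newick("((A:0.1,B:0.1):0.05,C:0.2);")
  expect_equal(length(tr2$tip.label), 3)
  expect_equal(tr2$Nnode, 2)
  expect_true(all(nzchar(tr2$node.label)))

  expect_error(read_newick("(A:0.1"), "parse")
  expect_error(read_newick("(A:0.1,A:0.2);"), "unique")
  expect_error(read_newick("(A,B);"), "branch lengths")
})

test_that("zero rates propagate the root unchanged to every tip", {
  set.seed(1)
  jc <- k80_model(1)
  root <- root_sequence(40, jc)
  hook <- node_hook(function(lab) TRUE, function(seq) {
    set_site_property(seq, seq_len(length(seq$states)), jc,
                      "rate_multiplier", 0)
  }, label = "freeze")
  sim <- simulate_evolution("(A:0.5,B:0.5);", root, hooks = hook, seed = 2)
  expect_identical(sim$nodes[["A"]]$states, sim$nodes[["Node1"]]$states)
  expect_identical(sim$nodes[["B"]]$states, sim$nodes[["Node1"]]$states)
  expect_equal(nrow(sim$events), 0)
})

test_that("nested branches compose like a single branch of the summed length", {
  # Markov additivity through the tree recursion: the state at a tip below
  # two stacked branches (0.2 at the internal node + 0.3 to the tip) is
  # distributed like a single 0.5 branch
  set.seed(2)
  k <- k80_model(2)
  tree <- read_newick("((A:0.3,Astub:0.0)X:0.2,Bstub:0.0);")
  n <- 3000
  chain_states <- character(n); single_states <- character(n)
  for (r in seq_len(n)) {
    root <- root_sequence_from_string("G", k)
    simc <- simulate_evolution(tree, root)
    chain_states[r] <- simc$nodes[["A"]]$states[1]
    single_states[r] <- evolve_single_site("G", k, 0.5)
  }
  lv <- c("A", "C", "G", "T")
  t1 <- table(factor(chain_states, levels = lv))
  t2 <- table(factor(single_states, levels = lv))
  expect_gt(suppressWarnings(chisq.test(rbind(t1, t2))$p.value), 0.01)
})

test_that("a hook halving multipliers halves the subtree's event count", {
  set.seed(3)
  jc <- k80_model(1)
  root <- root_sequence(1000, jc)
  tree <- read_newick(
    "((A1:0.4,A2:0.4)H:0.001,(B1:0.4,B2:0.4)K:0.001);")
  hook <- node_hook("H", function(seq) {
    set_site_property(seq, seq_len(length(seq$states)), jc,
                      "rate_multiplier", 0.5)
  }, label = "halve")
  sim <- simulate_evolution(tree, root, hooks = hook, seed = 4)
  ev <- sim$events
  nA <- sum(ev$branch %in% c("A1", "A2"))
  nB <- sum(ev$branch %in% c("B1", "B2"))
  # Poisson means 2 * 1000 * 0.4 * 0.5 = 400 and 800
  ratio <- nA / nB
  sd_ratio <- 0.5 * sqrt(1 / 400 + 1 / 800)
  expect_lt(abs(ratio - 0.5), 3 * sd_ratio)
})

test_that("hooks editing states or length are rejected by name", {
  set.seed(4)
  jc <- k80_model(1)
  root <- root_sequence(10, jc)
  bad <- node_hook(function(lab) TRUE, function(seq) {
    seq$states[1] <- "T"
  }, label = "vandal")
  expect_error(
    simulate_evolution("(A:0.1,B:0.1);", root, hooks = bad, seed = 1),
    "vandal")
})

test_that("alignments without indels are rectangular and gap-free", {
  set.seed(5)
  jc <- k80_model(1)
  root <- root_sequence(30, jc, label = "all")
  sim <- simulate_evolution("((A:0.2,B:0.2):0.1,C:0.3);", root, seed = 6)
  aln <- build_true_alignment(sim)
  expect_equal(ncol(aln$tokens), 30)
  expect_false(any(is.na(aln$tokens)))
  expect_equal(unname(nchar(aln$sequences)), rep(30, 3))
  expect_equal(unique(aln$annotation$partition), "all")
})

test_that("a deletion shows as gaps only in the affected lineage", {
  # hand-built simulation result: two tips, B lost sites 4..5
  ids <- 1:6
  tree <- read_newick("(A:1,B:1);")
  result <- structure(list(
    tree = tree,
    nodes = list(
      Node1 = list(ids = ids, states = strsplit("ACGTAC", "")[[1]],
                   labels = rep("p", 6)),
      A = list(ids = ids, states = strsplit("ACGTAC", "")[[1]],
               labels = rep("p", 6)),
      B = list(ids = ids[-c(4, 5)], states = strsplit("ACGC", "")[[1]],
               labels = rep("p", 4))
    ),
    tips = c("A", "B"),
    events = data.frame(),
    ops = list(A = list(), B = list(list(type = "deletion", ids = 4:5))),
    columns = ids,
    column_label = stats::setNames(rep("p", 6), as.character(ids)),
    root_label = "Node1"
  ), class = "gs_simulation")
  aln <- build_true_alignment(result)
  expect_equal(unname(aln$sequences[["A"]]), "ACGTAC")
  expect_equal(unname(aln$sequences[["B"]]), "ACG--C")
  expect_true(replay_alignment_ops(result))
  expect_equal(degap_row(aln, "B"), result$nodes$B$states)
})

test_that("mixed indel simulations keep alignment invariants", {
  set.seed(7)
  jc <- k80_model(2)
  for (rep in 1:5) {
    root <- root_sequence(60, jc, label = "all")
    del <- deletion_process(0.15, geometric_length(0.5))
    ins <- insertion_process(0.1, geometric_length(0.5),
                             template = list(model = jc))
    attach_process(root, 1, 60, del, deletion_tolerance = 0.7)
    attach_process(root, 1, 60, ins)
    sim <- simulate_evolution("((A:0.4,B:0.3):0.2,(C:0.3,D:0.4):0.1);",
                              root, seed = 100 + rep)
    aln <- build_true_alignment(sim, include_internal = TRUE,
                                drop_all_gap_columns = FALSE)
    for (lab in names(sim$nodes)) {
      # each row degaps to the node's exact sequence
      expect_identical(degap_row(aln, lab), sim$nodes[[lab]]$states)
      # homology soundness: the row's site identities appear in column order
      pos <- match(sim$nodes[[lab]]$ids, aln$column_ids)
      expect_false(anyNA(pos))
      expect_true(all(diff(pos) > 0))
    }
    # the alignment is reconstructible from the logged operations alone
    expect_true(replay_alignment_ops(sim))
    # tip alignment with dropping enabled has no all-gap columns
    tip_aln <- build_true_alignment(sim, drop_all_gap_columns = TRUE)
    expect_true(all(colSums(!is.na(tip_aln$tokens)) > 0))
  }
})

test_that("insertions on sibling branches occupy distinct columns", {
  set.seed(8)
  jc <- k80_model(1)
  root <- root_sequence_from_string("ACGT", jc)
  ins <- insertion_process(3, fixed_length(2), template = list(model = jc))
  attach_process(root, 1, 4, ins)
  sim <- simulate_evolution("(A:0.4,B:0.4);", root, seed = 9)
  insA <- sum(sim$events$kind == "insertion" & sim$events$accepted &
                sim$events$branch == "A")
  insB <- sum(sim$events$kind == "insertion" & sim$events$accepted &
                sim$events$branch == "B")
  expect_gt(insA, 0)
  expect_gt(insB, 0)
  aln <- build_true_alignment(sim, drop_all_gap_columns = FALSE)
  # total columns = root sites + every inserted site (non-homologous
  # insertions never share a column)
  expect_equal(ncol(aln$tokens), 4 + 2 * (insA + insB))
  expect_true(replay_alignment_ops(sim))
})
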