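# indel processes: lengths, proposals, field acceptance, fast-field scaling

test_that("length distributions sample their stated support", {
  expect_equal(sample_indel_length(fixed_length(3), 10), rep(3L, 10))
  expect_equal(sample_indel_length(geometric_length(1), 10), rep(1L, 10))

  set.seed(1)
  d <- table_length(c(1L, 2L), c(0.5, 0.5))
  draws <- sample_indel_length(d, 10000)
  expect_true(all(draws %in% c(1L, 2L)))
  expect_lt(abs(mean(draws) - 1.5), 3 * 0.5 / sqrt(10000))

  set.seed(2)
  g <- geometric_length(0.25)
  expect_lt(abs(mean(sample_indel_length(g, 20000)) - 4), 0.2)

  u <- user_length(function(n) rep(2L, n))
  expect_equal(sample_indel_length(u, 3), rep(2L, 3))
  bad <- user_length(function(n) rep(0L, n))
  expect_error(sample_indel_length(bad), "length < 1")
  expect_error(table_length(c(1, 2), c(0.5, 0.6)), "sum to 1")
  expect_error(fixed_length(0), ">= 1")
})

test_that("deletion spans anchor at the initiating site and truncate at the end", {
  s <- root_sequence_from_string("ACGTACGTAC", k80_model(1))
  del <- deletion_process(0.1, fixed_length(3))
  attach_process(s, 1, 10, del)

  sp <- propose_deletion(s, del, 4, length = 1)
  expect_equal(c(sp$from, sp$to), c(4, 4))
  expect_false(sp$truncated)

  sp <- propose_deletion(s, del, 5, length = 3)
  expect_equal(c(sp$from, sp$to), c(5, 7))

  sp <- propose_deletion(s, del, 10, length = 5)
  expect_equal(c(sp$from, sp$to), c(10, 10))
  expect_true(sp$truncated)
  expect_equal(sp$proposed_length, 5L)
})

test_that("field acceptance is the product of span tolerances", {
  s <- root_sequence_from_string("ACGTA", k80_model(1))
  del <- deletion_process(0.1, fixed_length(2))
  attach_process(s, 1, 5, del,
                 deletion_tolerance = c(0.5, 0.2, 1, 0, 1))

  expect_equal(deletion_acceptance_probability(
    s, propose_deletion(s, del, 1, length = 2), del), 0.1)
  expect_equal(deletion_acceptance_probability(
    s, propose_deletion(s, del, 3, length = 1), del), 1)
  # spans containing a d = 0 site are never accepted
  expect_equal(deletion_acceptance_probability(
    s, propose_deletion(s, del, 3, length = 2), del), 0)
  # unbound sites are neutral (d = 1): span crossing a partition boundary
  s2 <- root_sequence_from_string("ACGTA", k80_model(1))
  attach_process(s2, 1, 2, del, deletion_tolerance = 0.5)
  sp <- propose_deletion(s2, del, 2, length = 3)  # sites 2..4, 3:4 unbound
  expect_equal(deletion_acceptance_probability(s2, sp, del), 0.5)
})

test_that("fast field rescales proposals by the most tolerant site", {
  k <- k80_model(1)
  mk <- function(mode, tol) {
    s <- root_sequence_from_string("ACG", k)
    d <- deletion_process(0.3, fixed_length(1), mode = mode)
    attach_process(s, 1, 3, d, deletion_tolerance = tol)
    list(s = s, d = d)
  }
  plain <- mk("plain_field", c(0.1, 0.5, 0.2))
  fast <- mk("fast_field", c(0.1, 0.5, 0.2))
  expect_equal(effective_deletion_proposal_rate(plain$s, plain$d, 1), 0.3)
  expect_equal(effective_deletion_proposal_rate(fast$s, fast$d, 1),
               0.3 * 0.5)

  # with all tolerances 1 the two modes coincide
  p1 <- mk("plain_field", 1); f1 <- mk("fast_field", 1)
  expect_equal(effective_deletion_proposal_rate(f1$s, f1$d, 2),
               effective_deletion_proposal_rate(p1$s, p1$d, 2))

  # all tolerances 0: no proposals ever in fast mode
  f0 <- mk("fast_field", 0)
  expect_equal(effective_deletion_proposal_rate(f0$s, f0$d, 1), 0)

  # D follows tolerance edits (lazy cache invalidation)
  set_site_property(fast$s, 2, fast$d, "deletion_tolerance", 0.25)
  expect_equal(effective_deletion_proposal_rate(fast$s, fast$d, 1),
               0.3 * 0.25)
})

test_that("realized deletion rates are identical between plain and fast field", {
  # algebraic identity: rate * prod(d) == (rate * D) * (prod(d) / D),
  # and prod(d)/D <= 1 for every span
  set.seed(3)
  k <- k80_model(1)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    tol <- round(runif(n, 0, 1), 3)
    s_p <- root_sequence_from_string(paste(rep("A", n), collapse = ""), k)
    s_f <- root_sequence_from_string(paste(rep("A", n), collapse = ""), k)
    dp <- deletion_process(0.4, fixed_length(1), mode = "plain_field")
    df <- deletion_process(0.4, fixed_length(1), mode = "fast_field")
    attach_process(s_p, 1, n, dp, deletion_tolerance = tol)
    attach_process(s_f, 1, n, df, deletion_tolerance = tol)
    from <- sample(n, 1)
    len <- sample(1:4, 1)
    sp_p <- propose_deletion(s_p, dp, from, length = len)
    sp_f <- propose_deletion(s_f, df, from, length = len)
    acc_p <- deletion_acceptance_probability(s_p, sp_p, dp)
    acc_f <- deletion_acceptance_probability(s_f, sp_f, df)
    expect_lte(acc_f, 1)
    rate_p <- effective_deletion_proposal_rate(s_p, dp, from) * acc_p
    rate_f <- effective_deletion_proposal_rate(s_f, df, from) * acc_f
    expect_equal(rate_f, rate_p, tolerance = 1e-12)
  }
})

test_that("accept_or_reject is exact at the boundaries and unbiased inside", {
  expect_true(all(replicate(20, accept_or_reject(1))))
  expect_false(any(replicate(20, accept_or_reject(0))))
  expect_error(accept_or_reject(1.2), "\\[0, 1\\]")
  expect_error(accept_or_reject(-0.1), "\\[0, 1\\]")
  set.seed(4)
  hits <- mean(replicate(20000, accept_or_reject(0.3)))
  expect_lt(abs(hits - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
})

test_that("insertions draw template sites or user-generated payloads", {
  set.seed(5)
  k <- k80_model(2)
  ins <- insertion_process(0.1, fixed_length(4), template = list(model = k))
  s <- root_sequence_from_string("ACGTACGT", k)
  attach_process(s, 1, 8, ins)
  pay <- propose_insertion(s, ins, 3)
  expect_equal(pay$at, 3)
  expect_length(pay$states, 4)
  expect_true(all(pay$states %in% k$alphabet$symbols))
  expect_length(pay$bindings, 4)

  dup <- insertion_process(0.1, fixed_length(3),
                           generator = duplication_generator())
  attach_process(s, 1, 8, dup)
  pay <- propose_insertion(s, dup, 3, length = 3)
  expect_equal(pay$states, c("A", "C", "G"))  # copies the left flank

  bad <- insertion_process(0.1, fixed_length(2),
                           generator = function(length, context, seq) {
                             list(states = "A", bindings = list(list()))
                           }, label = "broken")
  attach_process(s, 1, 8, bad)
  expect_error(propose_insertion(s, bad, 1, length = 2), "broken")
  expect_error(insertion_process(0.1, fixed_length(1)), "template")
})

test_that("zero insertion tolerance gates insertions off", {
  set.seed(6)
  k <- k80_model(1)
  s <- root_sequence_from_string(strrep("A", 30), k)
  ins <- insertion_process(0.5, fixed_length(1), template = list(model = k))
  attach_process(s, 1, 30, ins, insertion_tolerance = 0)
  res <- evolve_branch(s, 1)
  ev <- res$events[res$events$kind == "insertion", ]
  expect_gt(nrow(ev), 0)          # insertions are proposed...
  expect_false(any(ev$accepted))  # ...but never applied
  expect_length(s$states, 30)
})

test_that("Monte-Carlo span acceptance matches the tolerance product", {
  set.seed(7)
  k <- k80_model(1)
  s <- root_sequence_from_string("ACGTA", k)
  del <- deletion_process(0.1, fixed_length(3))
  attach_process(s, 1, 5, del, deletion_tolerance = c(0.9, 0.4, 0.7, 1, 1))
  span <- propose_deletion(s, del, 1, length = 3)
  p <- deletion_acceptance_probability(s, span, del)
  expect_equal(p, 0.9 * 0.4 * 0.7, tolerance = 1e-12)
  n <- 20000
  freq <- mean(replicate(n, accept_or_reject(p)))
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
})
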