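# substitution model construction, normalization and analytic properties

model_normalization_ok <- function(m, tol = 1e-10) {
  expect_lt(max(abs(rowSums(m$Q))), tol)
  expect_lt(abs(sum(m$pi) - 1), tol)
  expect_lt(max(abs(as.numeric(m$pi %*% m$Q))), 1e-8)
  expect_lt(abs(sum(m$pi * -diag(m$Q)) - 1), tol)
}

test_that("general model solves the stationary distribution from the rates", {
  ab <- make_alphabet(c("A", "B"))
  m <- general_model(ab, matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(m$pi), c(0.75, 0.25), tolerance = 1e-12)
  model_normalization_ok(m)

  # any symmetric rate matrix has the uniform stationary distribution
  set.seed(11)
  for (k in c(3, 5, 8)) {
    R <- matrix(runif(k * k), k, k)
    R <- R + t(R)
    m <- general_model(make_alphabet(paste0("x", 1:k)), R)
    expect_equal(unname(m$pi), rep(1 / k, k), tolerance = 1e-9)
    model_normalization_ok(m)
  }
})

test_that("general model accepts multi-character tokens (stop-codon process)", {
  ab <- make_alphabet(c("TAA", "TAG", "TGA"))
  R <- matrix(0.1, 3, 3); diag(R) <- 0
  m <- general_model(ab, R, normalize = FALSE, label = "stop")
  expect_equal(unname(m$pi), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(m$Q["TAA", "TAG"], 0.1)    # unnormalized rates kept as given
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
})

test_that("general model validates its inputs", {
  ab <- make_alphabet(c("A", "B", "C"))
  R <- matrix(1, 3, 3)
  R[1, 2] <- -0.5
  expect_error(general_model(ab, R), "nonnegative")
  # C unreachable: no rates into or out of it
  R2 <- matrix(0, 3, 3); R2[1, 2] <- 1; R2[2, 1] <- 1
  expect_error(general_model(ab, R2), "C")
  # supplied pi must be stationary
  R3 <- matrix(1, 3, 3); diag(R3) <- 0
  expect_error(general_model(ab, R3, pi = c(0.7, 0.2, 0.1)), "stationary")
  expect_error(general_model(ab, R3[1:2, 1:2]), "3 x 3")
})

test_that("K80 has the kappa rate structure and JC as a special case", {
  jc <- k80_model(1)
  expect_true(all(abs(jc$Q[row(jc$Q) != col(jc$Q)] - 1 / 3) < 1e-12))
  k2 <- k80_model(2)
  expect_equal(k2$Q["A", "G"], 0.5, tolerance = 1e-12)   # transition
  expect_equal(k2$Q["A", "C"], 0.25, tolerance = 1e-12)  # transversion
  expect_equal(k2$Q["C", "T"] / k2$Q["C", "A"], 2, tolerance = 1e-12)
  for (kappa in c(0.5, 1, 2, 10)) model_normalization_ok(k80_model(kappa))
  expect_error(k80_model(0), "positive")
  expect_error(k80_model(-1), "positive")
})

test_that("GTR nests K80 and keeps supplied frequencies", {
  kappa <- 2.5
  g <- gtr_model(c(1, kappa, 1, 1, kappa, 1), rep(0.25, 4))
  k <- k80_model(kappa)
  expect_lt(max(abs(g$Q - k$Q)), 1e-12)

  skew <- gtr_model(c(1, 2, 0.5, 1.2, 3, 0.8), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(skew$pi), c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-15)
  model_normalization_ok(skew)
  expect_error(gtr_model(rep(1, 6), c(0.3, 0.3, 0.3, 0.2)), "summing to 1")
})

test_that("UNREST recovers stationary frequencies numerically", {
  # symmetric rates: uniform pi
  m <- unrest_model(rep(c(0.3, 0.7, 0.5), 4))
  sym <- matrix(0, 4, 4)
  sym[lower.tri(sym)] <- c(1, 2, 3, 4, 5, 6)
  sym <- sym + t(sym)
  ms <- unrest_model(sym)
  expect_equal(unname(ms$pi), rep(0.25, 4), tolerance = 1e-9)

  # rates of a GTR model: pi matches the GTR frequencies (model nesting)
  f <- c(0.1, 0.2, 0.3, 0.4)
  g <- gtr_model(c(1, 2, 0.5, 1.2, 3, 0.8), f)
  R <- g$Q; diag(R) <- 0
  mu <- unrest_model(R)
  expect_equal(unname(mu$pi), f, tolerance = 1e-8)

  set.seed(21)
  ma <- unrest_model(runif(12, 0.2, 2))
  expect_lt(max(abs(as.numeric(ma$pi %*% ma$Q))), 1e-8)
  model_normalization_ok(ma)
})

test_that("GY94 rates follow the single-change kappa/omega structure", {
  code <- standard_genetic_code()
  g <- gy94_model(kappa = 2, omega = 0.5)
  # >1 position differences are forbidden
  expect_equal(g$Q["AAA", "AGG"], 0)
  expect_equal(g$Q["AAA", "CCC"], 0)
  # AAA->AAG synonymous transition (kappa), AAA->AAT nonsynonymous
  # transversion (omega): ratio = kappa / omega
  expect_equal(code[["AAA"]], code[["AAG"]])
  expect_false(code[["AAA"]] == code[["AAT"]])
  expect_equal(g$Q["AAA", "AAG"] / g$Q["AAA", "AAT"], 2 / 0.5,
               tolerance = 1e-12)
  model_normalization_ok(g)

  # omega = 0: all nonsynonymous rates exactly zero
  g0 <- gy94_model(2, 0)
  aa <- code[g0$alphabet$symbols]
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(g0$Q[nonsyn] == 0))

  # kappa = 1, omega = 1, equal frequencies: all single-change rates equal
  g1 <- gy94_model(1, 1)
  off <- g1$Q[row(g1$Q) != col(g1$Q)]
  pos <- off[off > 0]
  expect_lt(diff(range(pos)), 1e-12)

  expect_error(gy94_model(0, 1), "kappa")
  expect_error(gy94_model(2, -0.1), "omega")
  bad_freqs <- stats::setNames(rep(1 / 62, 62),
                               c(g$alphabet$symbols, "TAA"))
  expect_error(gy94_model(2, 1, codon_freqs = bad_freqs), "TAA")
})

test_that("F3x4 codon frequencies are positive and sum to one", {
  f <- f3x4_codon_freqs(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_length(f, 61)
  m <- gy94_model(2, 0.3, codon_freqs = f)
  expect_equal(unname(m$pi), unname(f), tolerance = 1e-12)
})

test_that("empirical amino-acid models are valid and file I/O round-trips", {
  for (nm in c("WAG", "JTT", "LG")) {
    m <- empirical_aa_model(nm)
    expect_length(m$alphabet$symbols, 20)
    model_normalization_ok(m, tol = 1e-9)
  }

  # file with all exchangeabilities 1 and uniform frequencies: equal rates
  f <- tempfile(fileext = ".dat")
  lines <- c("# synthetic equal-rates model",
             vapply(1:19, function(i) paste(rep("1.0", i), collapse = " "),
                    character(1)),
             paste(rep("0.05", 20), collapse = " "))
  writeLines(lines, f)
  m <- empirical_aa_model(f)
  off <- m$Q[row(m$Q) != col(m$Q)]
  expect_lt(diff(range(off)), 1e-12)

  # write / reload reproduces exchangeabilities up to scale
  wag <- empirical_aa_model("WAG")
  f2 <- tempfile(fileext = ".dat")
  write_exchangeability_file(wag, f2)
  wag2 <- empirical_aa_model(f2)
  S1 <- sweep(wag$Q, 2, wag$pi, "/")
  S2 <- sweep(wag2$Q, 2, wag2$pi, "/")
  ratio <- S1[lower.tri(S1)] / S2[lower.tri(S2)]
  expect_lt(diff(range(ratio)), 1e-6)
  expect_equal(unname(wag2$pi), unname(wag$pi), tolerance = 1e-8)

  # malformed triangle: error naming the line
  f3 <- tempfile(fileext = ".dat")
  writeLines(c("1.0", "1.0 1.0 1.0"), f3)  # line 2 should have 2 values
  expect_error(empirical_aa_model(f3), "line 2")
})

test_that("transition probabilities match closed forms and the series oracle", {
  jc <- k80_model(1)
  expect_equal(transition_probabilities(jc, 0), diag(4),
               ignore_attr = TRUE)
  # ergodic limit: rows converge to pi
  k <- k80_model(3)
  Pinf <- transition_probabilities(k, 50)
  expect_lt(max(abs(sweep(Pinf, 2, k$pi, "-"))), 1e-6)
  # JC closed form for the diagonal
  P <- transition_probabilities(jc, 0.1)
  expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-4 * 0.1 / 3), 4),
               tolerance = 1e-12)
  expect_error(transition_probabilities(jc, -0.1), "nonnegative")

  # independent truncated power-series oracle on random models
  set.seed(31)
  for (k_states in c(2, 4, 7, 10)) {
    m <- random_model(k_states)
    for (t in c(0.05, 0.3, 1)) {
      P1 <- transition_probabilities(m, t)
      P2 <- powerseries_expm(m$Q, t)
      expect_lt(max(abs(P1 - P2)), 1e-8)
      expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
    }
  }
})

test_that("a long single-site chain converges to the stationary frequencies", {
  set.seed(41)
  m <- random_model(4)
  # jump-chain equilibrium via many independent long runs is slow; instead
  # evolve one site for a long time repeatedly from a fixed start and test
  # the end-state distribution against pi
  n <- 5000
  states <- character(n)
  for (r in seq_len(n)) states[r] <- evolve_single_site("s1", m, 15)
  obs <- table(factor(states, levels = m$alphabet$symbols))
  expect_gt(chisq_gof_p(as.numeric(obs), as.numeric(m$pi)), 0.001)
})
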