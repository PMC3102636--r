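# independent oracles and small utilities shared across tests

# truncated power series exp(Qt) = sum_{k<=kmax} (Qt)^k / k!
# (independent of the Pade-based transition_probabilities path)
powerseries_expm <- function(Q, t, kmax = 40L) {
  A <- Q * t
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(kmax)) {
    term <- term %*% A / k
    P <- P + term
  }
  P
}

# chi-square goodness-of-fit p-value for observed counts vs probabilities,
# pooling classes with tiny expectation
chisq_gof_p <- function(obs, probs) {
  n <- sum(obs)
  exp_counts <- n * probs
  keep <- exp_counts >= 1
  if (any(!keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    exp_counts <- c(exp_counts[keep], sum(exp_counts[!keep]))
  }
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

# two-sample chi-square homogeneity p-value on two count vectors binned to
# keep expected cell counts reasonable
chisq_two_sample_p <- function(x, y) {
  breaks <- unique(stats::quantile(c(x, y), probs = seq(0, 1, 0.125)))
  if (length(breaks) < 3) {
    lv <- sort(unique(c(x, y)))
    tx <- table(factor(x, levels = lv))
    ty <- table(factor(y, levels = lv))
  } else {
    cx <- cut(x, breaks = c(-Inf, breaks[-1]))
    cy <- cut(y, breaks = c(-Inf, breaks[-1]))
    tx <- table(cx); ty <- table(cy)
  }
  keep <- (tx + ty) > 0
  suppressWarnings(stats::chisq.test(rbind(tx[keep], ty[keep]))$p.value)
}

# end state of a single-site sequence evolved for time t (one replicate)
evolve_single_site <- function(token, model, t) {
  s <- root_sequence_from_string(token, model)
  evolve_branch(s, t, log_events = FALSE)
  s$states[1]
}

# a small random general model over k states (normalized)
random_model <- function(k) {
  ab <- make_alphabet(paste0("s", seq_len(k)))
  R <- matrix(stats::runif(k * k, 0.1, 1), k, k)
  general_model(ab, R, label = paste0("random", k))
}
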