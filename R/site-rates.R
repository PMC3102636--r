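# ---- among-site rate variation ---------------------------------------------

#' Among-site rate variation models
#'
#' Describes how per-site rate multipliers are drawn. Supported kinds:
#' \describe{
#'   \item{constant}{all multipliers 1.}
#'   \item{discrete_gamma}{the classic discrete-gamma approximation with
#'     `n_categories` equal-probability categories; each category is
#'     represented by its conditional mean, so the average multiplier is
#'     exactly 1.}
#'   \item{continuous_gamma}{one multiplier per site drawn from
#'     Gamma(shape = alpha, rate = alpha) (mean 1).}
#'   \item{invariant_plus_gamma}{a site is invariant (multiplier 0) with
#'     probability `p_inv`, otherwise gamma-distributed with mean
#'     `1/(1 - p_inv)`, keeping the marginal mean at 1.}
#'   \item{custom}{an arbitrary rule: a function of the site index returning
#'     a nonnegative multiplier, evaluated with the current RNG so any R
#'     expression can drive the rates.}
#' }
#'
#' @param kind one of the kinds above.
#' @param alpha gamma shape (> 0), required for the gamma kinds.
#' @param n_categories number of discrete-gamma categories (default 4).
#' @param p_inv proportion of invariant sites in `[0, 1]`.
#' @param rule function(site_index) -> nonnegative multiplier, for
#'   `kind = "custom"`.
#' @return an object of class `gs_rate_model`; for `discrete_gamma` it also
#'   carries `category_rates`.
#' @export
site_rate_model <- function(kind = c("constant", "discrete_gamma",
                                     "continuous_gamma",
                                     "invariant_plus_gamma", "custom"),
                            alpha = NULL, n_categories = 4L, p_inv = 0,
                            rule = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("discrete_gamma", "continuous_gamma",
                  "invariant_plus_gamma")) {
    needs_alpha <- !(kind == "invariant_plus_gamma" && p_inv >= 1)
    if (needs_alpha && (is.null(alpha) || !is.numeric(alpha) || alpha <= 0)) {
      stop("gamma rate models require alpha > 0", call. = FALSE)
    }
  }
  if (kind == "discrete_gamma" &&
      (n_categories < 1L || n_categories != round(n_categories))) {
    stop("n_categories must be a positive integer", call. = FALSE)
  }
  if (p_inv < 0 || p_inv > 1) {
    stop("p_inv must be in [0, 1]", call. = FALSE)
  }
  if (kind == "custom" && !is.function(rule)) {
    stop("kind = 'custom' requires a rule function", call. = FALSE)
  }
  m <- structure(
    list(kind = kind, alpha = alpha, n_categories = as.integer(n_categories),
         p_inv = p_inv, rule = rule),
    class = "gs_rate_model"
  )
  if (kind == "discrete_gamma") {
    m$category_rates <- discrete_gamma_rates(alpha, m$n_categories)
  }
  m
}

#' Discrete-gamma category rates (conditional means)
#'
#' Rates of `k` equal-probability categories of a Gamma(alpha, alpha)
#' distribution, each represented by its conditional mean, so
#' `mean(rates) == 1` exactly.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @return numeric vector of length `k`.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  k <- as.integer(k)
  if (k == 1L) return(1)
  bounds <- c(0, stats::qgamma(seq_len(k - 1) / k, alpha, alpha), Inf)
  # E[X | a < X <= b] * P(a < X <= b) = F_{alpha+1}(b) - F_{alpha+1}(a)
  # for X ~ Gamma(alpha, alpha) with mean 1
  k * diff(stats::pgamma(bounds, alpha + 1, alpha))
}

#' Draw site-specific rate multipliers
#'
#' @param rate_model a [site_rate_model()].
#' @param n number of sites (>= 1).
#' @return numeric vector of `n` nonnegative multipliers; deterministic
#'   given the RNG state (`set.seed`).
#' @export
draw_site_rates <- function(rate_model, n) {
  stopifnot(inherits(rate_model, "gs_rate_model"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  switch(rate_model$kind,
    constant = rep(1, n),
    discrete_gamma = sample(rate_model$category_rates, n, replace = TRUE),
    continuous_gamma = stats::rgamma(n, rate_model$alpha, rate_model$alpha),
    invariant_plus_gamma = {
      p <- rate_model$p_inv
      inv <- stats::runif(n) < p
      r <- numeric(n)
      if (any(!inv)) {
        if (p >= 1) {
          # unreachable: runif < 1 almost surely, kept for completeness
          r[!inv] <- 0
        } else {
          r[!inv] <- stats::rgamma(sum(!inv), rate_model$alpha,
                                   rate_model$alpha * (1 - p))
        }
      }
      r
    },
    custom = {
      r <- vapply(seq_len(n), rate_model$rule, numeric(1))
      bad <- which(r < 0)
      if (length(bad)) {
        stop("custom rate rule returned a negative multiplier at site ",
             bad[1], call. = FALSE)
      }
      r
    }
  )
}
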