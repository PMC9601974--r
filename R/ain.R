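#' Active information of an event
#'
#' The test statistic of the learning framework:
#' `I+(A) = log P(A) / P0(A)`, the log-ratio of the agent's belief in the
#' event to the ignorance baseline's.  Positive values mean the agent
#' believes the proposition more strongly than a maximally ignorant person.
#' The value is `-Inf` exactly when `P(A) = 0` with `P0(A) > 0`; `+Inf` is
#' impossible by construction since `P(A) <= 1` and the value is bounded
#' above by `-log P0(A)`.  Logarithms are natural by default.
#'
#' @param P The agent's [belief_measure()].
#' @param P0 The ignorance baseline [belief_measure()].
#' @param region The proposition's [truth_region()] `A` (with
#'   `P0(A) > 0`).
#' @param base Logarithm base (`exp(1)` for nats, `2` for bits).
#' @return An object of class `ain` with fields `value`, `P_A`, `P0_A`,
#'   `base`.
#' @examples
#' sp <- world_space(points = c("x1", "x2", "x3"), x0 = "x2")
#' A <- truth_region(sp, points = c("x2", "x3"))
#' P <- belief_measure(sp, mass = c(0.2, 0.4, 0.4))
#' active_info(P, uniform_prior(sp), A)
#' @export
active_info <- function(P, P0, region, base = exp(1)) {
  p <- region_prob(P, region)
  p0 <- region_prob(P0, region)
  if (p0 <= 0)
    stop("undefined active information: P0(A) = 0", call. = FALSE)
  value <- if (p <= 0) -Inf else log(p / p0) / log(base)
  structure(list(value = value, P_A = p, P0_A = p0, base = base),
            class = "ain")
}

#' @export
print.ain <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$base, 2))) "bits" else "nats"
  cat(sprintf("I+ = %s %s  [P(A) = %.6g, P0(A) = %.6g]\n",
              format(x$value, digits = 6L), unit, x$P_A, x$P0_A))
  invisible(x)
}

ain_value <- function(x) if (inherits(x, "ain")) x$value else as.numeric(x)

#' Functional information of an event
#'
#' `-log P0(A)`: the information content of the event under the ignorance
#' baseline, and the maximal active information attainable for a true
#' proposition (the full-learning bound).
#'
#' @inheritParams active_info
#' @return Non-negative number.
#' @export
functional_information <- function(P0, region, base = exp(1)) {
  p0 <- region_prob(P0, region)
  if (p0 <= 0) stop("zero-probability region", call. = FALSE)
  -log(p0) / log(base)
}

#' Specification of the learning hypothesis test
#'
#' The test of H0 "the proposition is true" against H1 "it is false"
#' rejects H0 when `I+(A) <= I` for a threshold `I`.  The threshold may be
#' given directly, as a posterior-probability bound `p` (reject when
#' `P(A) <= p`, so `I = log(p / P0(A))`), or as a posterior-odds threshold
#' `r` / cost pair `(C0, C1)` with `r = C0 / C1`, which maps to
#' `I = -log(P0(A) (1 + r))` and makes the test identical to the Bayesian
#' odds rule.
#'
#' @param region The [truth_region()] `A`.
#' @param P0 The baseline measure (needed to convert `p` or `r`).
#' @param threshold Direct threshold `I` (extended real; `-Inf` allowed).
#' @param p Posterior-probability bound.
#' @param odds Posterior-odds threshold `r`.
#' @param costs Length-2 cost pair `c(C0, C1)`.
#' @param base Logarithm base.
#' @return An object of class `ain_test_spec` with fields `region`,
#'   `threshold`, `base`.
#' @export
test_spec <- function(region, P0 = NULL, threshold = NULL, p = NULL,
                      odds = NULL, costs = NULL, base = exp(1)) {
  stopifnot(inherits(region, "truth_region"))
  given <- !c(is.null(threshold), is.null(p),
              is.null(odds) && is.null(costs))
  if (sum(given) != 1L)
    stop("give exactly one of threshold, p, or odds/costs", call. = FALSE)
  if (is.null(threshold)) {
    p0 <- region_prob(P0, region)
    if (p0 <= 0) stop("P0(A) must be positive", call. = FALSE)
    if (!is.null(p)) {
      threshold <- log(p / p0) / log(base)
    } else {
      if (is.null(odds)) odds <- costs[1L] / costs[2L]
      threshold <- -log(p0 * (1 + odds)) / log(base)
    }
  }
  structure(list(region = region, threshold = threshold, base = base),
            class = "ain_test_spec")
}

#' Decide the learning hypothesis test
#'
#' Rejects H0 ("the proposition is true") iff the observed active
#' information is at or below the threshold; exact equality rejects.
#'
#' @param ain An [active_info()] result (or a number).
#' @param spec A [test_spec()].
#' @return `"reject_H0"` or `"retain_H0"`.
#' @export
ain_test <- function(ain, spec) {
  stopifnot(inherits(spec, "ain_test_spec"))
  v <- ain_value(ain)
  if (v <= spec$threshold) "reject_H0" else "retain_H0"
}

#' Type I / II error rates of the learning test
#'
#' Probabilities, over data generated in the true world, of wrongly
#' rejecting a true H0 (`alpha`, defined when `x0` is in `A`) or of
#' retaining a false H0 (`beta = Pr[I+ > I]`, defined when `x0` is outside
#' `A`).  `"enumerate"` is exact over the model's outcomes;
#' `"monte_carlo"` draws seeded data sets.
#'
#' @param model A [likelihood_model()].
#' @param prior The prior [belief_measure()].
#' @param spec A [test_spec()].
#' @param method `"enumerate"` or `"monte_carlo"`.
#' @param reps Monte Carlo replicates.
#' @param seed Integer seed (required for Monte Carlo).
#' @param x0 True world (defaults to the space's).
#' @return An object of class `error_rates`: list with `alpha` or `beta`,
#'   `method`, `reps`, `seed`.
#' @export
error_rates <- function(model, prior, spec,
                        method = c("enumerate", "monte_carlo"),
                        reps = 1e4, seed = NULL, x0 = prior$space$x0) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ain_test_spec"))
  space <- prior$space
  x0_in <- spec$region$contains(x0) > 0
  reject_prob <- function(draws, wts) {
    rej <- vapply(seq_along(draws), function(i) {
      d <- if (is.list(draws)) draws[[i]] else draws[i]
      post <- posterior_update(prior, model, d)
      a <- active_info(post, prior, spec$region, base = spec$base)
      ain_test(a, spec) == "reject_H0"
    }, TRUE)
    sum(wts[rej])
  }
  if (method == "enumerate") {
    if (is.null(model$outcomes))
      stop("enumerate method needs an enumerable data space", call. = FALSE)
    wts <- vapply(model$outcomes, function(d) lik_at(model, space, d, x0), 1)
    pr <- reject_prob(model$outcomes, wts)
  } else {
    if (is.null(seed))
      stop("monte_carlo method requires a seed", call. = FALSE)
    set.seed(seed)
    if (!is.null(model$outcomes)) {
      p <- vapply(model$outcomes, function(d) lik_at(model, space, d, x0), 1)
      idx <- sample.int(length(model$outcomes), reps, TRUE, prob = p)
      tab <- table(idx)
      pr <- reject_prob(model$outcomes[as.integer(names(tab))],
                        as.numeric(tab) / reps)
    } else {
      if (is.null(model$sampler))
        stop("monte_carlo needs enumerable outcomes or a sampler",
             call. = FALSE)
      draws <- model$sampler(reps, x0)
      pr <- reject_prob(draws, rep(1 / reps, length(draws)))
    }
  }
  out <- list(method = method, reps = if (method == "monte_carlo") reps,
              seed = seed, x0_in_A = x0_in)
  if (x0_in) out$alpha <- pr else out$beta <- 1 - pr
  structure(out, class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  if (x$x0_in_A) cat(sprintf("type I error alpha = %.6g", x$alpha))
  else cat(sprintf("type II error beta = %.6g", x$beta))
  cat(" [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Posterior odds, prior odds and Bayes factor
#'
#' The Bayesian view of the same test: posterior odds
#' `(1 - P(A)) / P(A)` factor into prior odds times the Bayes factor.  The
#' active information is the monotone transform
#' `I+ = -log[P0(A) (1 + odds)]` of the posterior odds, making the
#' frequentist threshold test and the Bayesian odds rule equivalent.
#'
#' @inheritParams active_info
#' @return List with `odds`, `prior_odds`, `bayes_factor` and a logical
#'   `infinite_odds` flag (when `P(A) = 0`).
#' @export
posterior_odds <- function(P, P0, region) {
  p <- region_prob(P, region)
  p0 <- region_prob(P0, region)
  if (p <= 0)
    return(list(odds = Inf, prior_odds = (1 - p0) / p0, bayes_factor = Inf,
                infinite_odds = TRUE))
  list(odds = (1 - p) / p, prior_odds = (1 - p0) / p0,
       bayes_factor = ((1 - p) / p) / ((1 - p0) / p0),
       infinite_odds = FALSE)
}

#' Kullback-Leibler form of expected active information
#'
#' The posterior expectation of the active information of the singleton
#' truth set equals the Kullback-Leibler divergence `D_KL(P || P0)`, also
#' the difference between the cross entropy `H(P, P0)` and the entropy
#' `H(P)`.  Non-negative; zero exactly when `P = P0`.  Returns `Inf` when
#' `P` puts mass where `P0` has none (including atoms absent from `P0`).
#'
#' @inheritParams active_info
#' @return Non-negative number (possibly `Inf`).
#' @export
kl_ain <- function(P, P0, base = exp(1)) {
  if (!is.null(P$atoms) && sum(P$atoms$w) > 1e-12 && is.null(P0$atoms))
    return(Inf)
  p <- P$mass
  p0 <- P0$mass
  if (any(p > 1e-12 & p0 <= 0)) return(Inf)
  pos <- p > 0 & p0 > 0
  max(sum(p[pos] * log(p[pos] / p0[pos])) / log(base), 0)
}

#' Mutual-information form of expected active information
#'
#' Averaging the Kullback-Leibler form over data sets drawn from the
#' agent's joint distribution `dQ = dP0 L` gives the mutual information
#' `I(X; D)` between the world parameter and the data.  Computed exactly by
#' a double sum over worlds and enumerable outcomes.
#'
#' @param prior A [belief_measure()].
#' @param model A [likelihood_model()] with enumerable outcomes.
#' @param base Logarithm base.
#' @return Non-negative number.
#' @export
mutual_info_ain <- function(prior, model, base = exp(1)) {
  if (is.null(model$outcomes))
    stop("mutual information needs an enumerable data space", call. = FALSE)
  space <- prior$space
  mi <- 0
  for (i in seq_along(model$outcomes)) {
    d <- if (is.list(model$outcomes)) model$outcomes[[i]] else
      model$outcomes[i]
    lv <- lik_values(model, space, d)
    ld <- sum(prior$mass * lv)
    if (ld <= 0) next
    pos <- prior$mass > 0 & lv > 0
    mi <- mi + sum(prior$mass[pos] * lv[pos] * log(lv[pos] / ld))
  }
  max(mi / log(base), 0)
}

#' Log likelihood-ratio statistic for the proposition
#'
#' The purely frequentist counterpart of the learning test:
#' `Lambda = -2 log[ max_{x in A} L(D|x) / max_{x in X} L(D|x) ] >= 0`,
#' maximised by grid search over the space (cells with positive region
#' coverage count as inside `A`; ties break toward the smallest index).
#'
#' @param model A [likelihood_model()].
#' @param region A non-empty [truth_region()].
#' @param data Observed data value.
#' @return Non-negative number.
#' @export
lr_statistic <- function(model, region, data) {
  space <- region$space
  lv <- lik_values(model, space, data)
  inside <- region$frac > 0
  if (!any(inside)) stop("empty region", call. = FALSE)
  max_a <- max(lv[inside])
  max_x <- max(lv)
  if (max_x <= 0) stop("likelihood vanishes everywhere", call. = FALSE)
  max(-2 * log(max_a / max_x), 0)
}
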