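#' Student assessment model
#'
#' Three possible worlds for a student taking a multiple-choice test: the
#' student guesses (`x1`), knows the material (`x2`), or gets external
#' help (`x3`).  The score is binomial with a per-question success
#' probability depending on the world; since skilled and helped students
#' score alike, the teacher's discernment cannot separate `x2` from `x3`
#' on the score alone.  A second-step helper signal `z2` (did the student
#' get help?) separates them.
#'
#' @param pi Success probabilities for the three worlds (each in (0, 1)).
#' @param questions Number of test questions.
#' @param x0 The true world label.
#' @return List with the space, the score model (step 1), the helper
#'   signal model (step 2), the step discernments and the two canonical
#'   truth regions (`scores_well` = `{x2, x3}`, `knows` = `{x2}`).
#' @export
student_model <- function(pi = c(0.5, 0.8, 0.8), questions = 10L,
                          x0 = "x2") {
  stopifnot(length(pi) == 3L, all(pi > 0 & pi < 1))
  labels <- c("x1", "x2", "x3")
  space <- world_space(points = labels, x0 = x0)
  # worlds with identical success probability are indistinguishable from
  # the score, so the score likelihood is measurable w.r.t. this partition
  groups <- split(labels, match(pi, unique(pi)))
  G1 <- discernment(space, cells = unname(groups), label = "score")
  score_model <- likelihood_model(
    lik = function(d, worlds) stats::dbinom(d, questions,
                                            pi[match(worlds, labels)]),
    outcomes = 0:questions, measurability = G1, label = "binomial score")
  helper_model <- likelihood_model(
    lik = function(z, worlds) {
      if (z == 1) as.numeric(worlds == "x3")
      else as.numeric(worlds %in% c("x1", "x2"))
    },
    outcomes = c(0L, 1L), label = "helper signal")
  list(space = space, score_model = score_model,
       helper_model = helper_model,
       G1 = G1, G2 = discernment_finest(space),
       region_scores_well = truth_region(space, points = c("x2", "x3"),
                                         label = "scores well"),
       region_knows = truth_region(space, points = "x2",
                                   label = "knows addition"),
       pi = pi, questions = questions)
}

#' Student assessment experiment
#'
#' Two-step discernment and data collection: the observed score `d1`
#' yields the step-1 posterior (constrained to the score discernment); an
#' optional helper signal `z2` yields the step-2 posterior under full
#' discernment.  Data sets are nested (`d2 = (d1, z2)`).
#'
#' @param d1 Observed score in `0..questions`.
#' @param z2 Optional helper signal (1 = the student got help, 0 = not).
#' @param model A [student_model()].
#' @param proposition Which truth set drives the trajectory:
#'   `"scores_well"` (`A = {x2, x3}`) or `"knows"` (`A = {x2}`).
#' @return A [trajectory_record()] with extra fields `P0`, `posteriors`,
#'   `d1`, `z2`.
#' @examples
#' tr <- student_experiment(d1 = 7)
#' tr$P_A
#' @export
student_experiment <- function(d1, z2 = NULL, model = student_model(),
                               proposition = c("scores_well", "knows")) {
  proposition <- match.arg(proposition)
  if (!(d1 %in% model$score_model$outcomes))
    stop("d1 must be an attainable score", call. = FALSE)
  P0 <- uniform_prior(model$space)
  P1 <- posterior_update(P0, model$score_model, d1)
  measures <- list(P1)
  discernments <- list(model$G1)
  data <- list(d1)
  if (!is.null(z2)) {
    if (!(z2 %in% c(0L, 1L)))
      stop("impossible data: z2 must be 0 or 1", call. = FALSE)
    P2 <- posterior_update(P1, model$helper_model, z2)
    measures <- c(measures, list(P2))
    discernments <- c(discernments, list(model$G2))
    data <- c(data, list(c(d1, z2)))
  }
  region <- if (proposition == "scores_well") model$region_scores_well
            else model$region_knows
  tr <- trajectory_record(region, P0, measures,
                          metric = world_metric("categorical"),
                          discernments = discernments, data = data,
                          nested_data = TRUE)
  tr$posteriors <- measures
  tr$d1 <- d1
  tr$z2 <- z2
  tr$model <- model
  tr
}

#' Binomial coin model on the unit interval
#'
#' Likelihood model for the number of heads in `k` tosses of a coin whose
#' heads probability is the world parameter.
#'
#' @param k Number of tosses.
#' @param resolution Grid cells for the parameter space.
#' @param x0 True heads probability.
#' @return List with the `space` and the [likelihood_model()].
#' @export
coin_model <- function(k, resolution = 1000L, x0 = 0.5) {
  space <- world_space(bounds = c(0, 1), resolution = resolution, x0 = x0)
  model <- likelihood_model(
    lik = function(m, worlds) stats::dbinom(m, k, worlds[, 1L]),
    outcomes = 0:k,
    sampler = function(n, x0) stats::rbinom(n, k, x0),
    label = sprintf("heads in %d tosses", k))
  list(space = space, model = model)
}

#' Coin tossing experiment
#'
#' Simulates `k_max` tosses of a coin with heads probability `x0` and
#' tracks the agent's Beta posterior belief in the proposition "the coin
#' is symmetric with margin eps" (`A = [0.5 - eps, 0.5 + eps]`) after each
#' toss: `Pk ~ Beta(1 + Mk, 1 + k - Mk)` under the uniform prior, so
#' `Pk(A)` and all ball probabilities are exact Beta integrals.
#'
#' @param x0 True heads probability in `[0, 1]`.
#' @param eps Symmetry margin in `(0, 0.5)`.
#' @param k_max Number of tosses.
#' @param seed Integer seed (mandatory).
#' @param k_grid Steps at which to record (default: every toss).
#' @param resolution Grid resolution of the companion parameter space.
#' @param n_eps Radii in the ball grid.
#' @return A [trajectory_record()] with extra fields `heads`
#'   (cumulative at the recorded steps), `x0`, `eps`, `seed`.
#' @export
coin_experiment <- function(x0 = 0.5, eps = 0.1, k_max = 1000L, seed,
                            k_grid = NULL, resolution = 1000L,
                            n_eps = 16L) {
  stopifnot(x0 >= 0, x0 <= 1, eps > 0, eps < 0.5)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  space <- world_space(bounds = c(0, 1), resolution = resolution, x0 = x0)
  region <- region_box(space, max(0, 0.5 - eps), min(1, 0.5 + eps),
                       label = "symmetric coin")
  P0_A <- min(1, 0.5 + eps) - max(0, 0.5 - eps)
  eps_grid <- exp(seq(log(1 / resolution), log(1), length.out = n_eps))
  ball_lo <- pmax(0, x0 - eps_grid)
  ball_hi <- pmin(1, x0 + eps_grid)
  ball0 <- ball_hi - ball_lo
  if (k_max == 0L) {
    tr <- trajectory_from_values(space, region, k = 0L, P_A = P0_A,
                                 P0_A = P0_A,
                                 ball = matrix(ball0, nrow = 1L),
                                 ball0 = ball0, eps_grid = eps_grid)
    tr$heads <- 0L; tr$x0 <- x0; tr$eps <- eps; tr$seed <- seed
    return(tr)
  }
  tosses <- stats::rbinom(k_max, 1L, x0)
  M <- cumsum(tosses)
  if (is.null(k_grid)) k_grid <- seq_len(k_max)
  k_grid <- sort(unique(as.integer(k_grid)))
  m <- M[k_grid]
  a <- 1 + m
  b <- 1 + k_grid - m
  P_A <- stats::pbeta(min(1, 0.5 + eps), a, b) -
    stats::pbeta(max(0, 0.5 - eps), a, b)
  ball_mat <- vapply(seq_along(eps_grid), function(j)
    stats::pbeta(ball_hi[j], a, b) - stats::pbeta(ball_lo[j], a, b),
    numeric(length(k_grid)))
  ball_mat <- matrix(ball_mat, nrow = length(k_grid))
  tr <- trajectory_from_values(space, region, k = k_grid, P_A = P_A,
                               P0_A = P0_A, ball = ball_mat, ball0 = ball0,
                               eps_grid = eps_grid)
  tr$heads <- m
  tr$x0 <- x0
  tr$eps <- eps
  tr$seed <- seed
  tr
}

#' Historical dating experiment
#'
#' An agent asks whether an ancestor died during a famine `[a, b]`.  Step
#' 1: radiometric dating with precision `delta = 1/N` constrains the
#' posterior to be piecewise constant on the `N` dating cells; the weights
#' may be dating-optimal (all weight on the true cell), systematically
#' biased by `-delta` (all weight on the previous cell, a
#' true-world-excluding measure), uniform, or user supplied.  Step 2: a
#' book states the time of death; a reliable book gives the point mass at
#' the true time, an unreliable one a mixture of a wrong-time point mass
#' and the step-1 measure.
#'
#' @param delta Dating precision `1/N` (N integer).
#' @param famine Famine interval `c(a, b)` inside `[0, 1]`.
#' @param x0 True time of death.
#' @param step1 `"optimal"`, `"biased"`, `"uniform"`, or a length-`N`
#'   weight vector.
#' @param book `"reliable"` or `"unreliable"`.
#' @param book_wrong_time Wrong time stated by an unreliable book
#'   (defaults to the midpoint of the biased cell).
#' @param book_weight Mixture weight given to the wrong-time point mass.
#' @param subcells Grid cells per dating cell.
#' @return A [trajectory_record()] with extra fields `delta`, `famine`,
#'   `weights` (step-1 cell weights) and `eq_check` (the closed-form
#'   strong-learning inequality values when the famine endpoints align
#'   with the dating cells, otherwise a note that the check was skipped).
#' @export
dating_experiment <- function(delta = 0.1, famine = c(0.3, 0.6), x0 = 0.47,
                              step1 = c("optimal", "biased", "uniform"),
                              book = c("reliable", "unreliable"),
                              book_wrong_time = NULL, book_weight = 0.5,
                              subcells = 20L) {
  N <- round(1 / delta)
  if (abs(N * delta - 1) > 1e-9)
    stop("delta must be 1/N for an integer N", call. = FALSE)
  a <- famine[1L]; b <- famine[2L]
  stopifnot(a >= 0, a < b, b <= 1)
  book <- match.arg(book)
  space <- world_space(bounds = c(0, 1), resolution = N * subcells, x0 = x0)
  P0 <- uniform_prior(space)
  G1 <- discernment_quantize(space, delta)
  i0 <- min(floor(x0 / delta) + 1L, N)
  if (is.character(step1)) {
    step1 <- match.arg(step1)
    w <- switch(step1,
      optimal = { v <- rep(0, N); v[i0] <- 1; v },
      biased = {
        if (i0 == 1L) stop("cannot bias below the first cell", call. = FALSE)
        v <- rep(0, N); v[i0 - 1L] <- 1; v
      },
      uniform = rep(1 / N, N))
  } else {
    w <- as.numeric(step1)
    if (length(w) != N || any(w < 0))
      stop("step1 weights must be N non-negative numbers", call. = FALSE)
    w <- w / sum(w)
  }
  P1 <- belief_measure(space, mass = rep(w / subcells, each = subcells))
  P2 <- if (book == "reliable") point_mass(space) else {
    wrong <- book_wrong_time %||% ((i0 - 1.5) * delta)
    mix <- point_mass(space, wrong)
    belief_measure(space, mass = (1 - book_weight) * P1$mass,
                   atoms = list(x = list(as.numeric(wrong)),
                                w = book_weight),
                   normalize = FALSE)
  }
  region <- region_box(space, a, b, label = "famine")
  tr <- trajectory_record(region, P0, list(P1, P2),
                          discernments = list(G1, discernment_finest(space)),
                          data = list("radiometric", c("radiometric", "book")))
  ia <- a * N; ib <- b * N
  tr$eq_check <- if (abs(ia - round(ia)) < 1e-9 && abs(ib - round(ib)) < 1e-9) {
    inside <- sum(w[(round(ia) + 1L):round(ib)])
    list(aligned = TRUE,
         I1_plus = if (inside > 0) log(inside / (b - a)) else -Inf,
         I2_plus = if (region_prob(P2, region) > 0)
           log(region_prob(P2, region) / (b - a)) else -Inf)
  } else {
    list(aligned = FALSE,
         note = "famine endpoints do not align with dating cells; closed-form check skipped")
  }
  tr$delta <- delta
  tr$famine <- famine
  tr$weights <- w
  tr
}

#' Youth camp weather experiment
#'
#' Two-day camp: outdoor activities are possible when both normalised
#' temperatures fall in `[a, b]`, so `A = [a, b]^2` on `X = (0, 1]^2`.
#' Step 1: a weather forecast with per-day precisions `delta = (d1, d2)`
#' (the second day is forecast further ahead, `d2 > d1`) constrains the
#' posterior to be constant on `d1 x d2` rectangles; step 2 is an
#' arbitrary full-discernment measure — a truthful prophet (point mass at
#' the true temperatures) or a biased ellipse-supported one.
#'
#' @param delta Per-day forecast precisions `c(d1, d2)` with `d2 > d1`,
#'   each `1/N`.
#' @param ab Activity temperature range `c(a, b)`.
#' @param x0 True temperatures of the two days.
#' @param forecast `"optimal"` or an `N1 x N2` weight matrix over forecast
#'   rectangles.
#' @param prophet `"truthful"`, `"ellipse"`, or a [belief_measure()] on
#'   the same space.
#' @param ellipse_center,ellipse_radii Support of the `"ellipse"` preset
#'   (defaults: offset from the true temperatures, radii 0.05).
#' @param resolution Grid resolution per dimension (must align with both
#'   precisions; default chosen automatically).
#' @return A [trajectory_record()] with extra field `prediction_prob`
#'   (probability per step that the camp leaders' outdoor/indoor call is
#'   correct).
#' @export
camp_experiment <- function(delta = c(0.1, 0.2), ab = c(0.2, 0.8),
                            x0 = c(0.55, 0.55),
                            forecast = "optimal", prophet = "truthful",
                            ellipse_center = NULL, ellipse_radii = c(0.05, 0.05),
                            resolution = NULL) {
  stopifnot(length(delta) == 2L, delta[2L] > delta[1L])
  N <- round(1 / delta)
  if (any(abs(N * delta - 1) > 1e-9))
    stop("each precision must be 1/N for an integer N", call. = FALSE)
  if (is.null(resolution))
    resolution <- N * ceiling(100 / N)
  space <- world_space(bounds = rbind(c(0, 1), c(0, 1)),
                       resolution = resolution, x0 = x0)
  P0 <- uniform_prior(space)
  G1 <- discernment_quantize(space, delta)
  if (identical(forecast, "optimal")) {
    P1 <- g_optimal(space, G1, P0)
  } else {
    wmat <- as.matrix(forecast)
    if (!all(dim(wmat) == N))
      stop("forecast weights must be an N1 x N2 matrix", call. = FALSE)
    ctr <- cell_centers(space)
    i <- pmin(floor(ctr[, 1L] / delta[1L]) + 1L, N[1L])
    j <- pmin(floor(ctr[, 2L] / delta[2L]) + 1L, N[2L])
    P1 <- belief_measure(space, mass = wmat[cbind(i, j)])
  }
  if (inherits(prophet, "belief_measure")) {
    P2 <- prophet
  } else if (identical(prophet, "truthful")) {
    P2 <- point_mass(space)
  } else if (identical(prophet, "ellipse")) {
    ctr0 <- ellipse_center %||%
      pmin(pmax(x0 - 0.25, ab[1L] + 0.06), ab[2L] - 0.06)
    ctr <- cell_centers(space)
    inside <- ((ctr[, 1L] - ctr0[1L]) / ellipse_radii[1L])^2 +
      ((ctr[, 2L] - ctr0[2L]) / ellipse_radii[2L])^2 <= 1
    P2 <- belief_measure(space, mass = as.numeric(inside))
  } else stop("unknown prophet specification", call. = FALSE)
  region <- region_box(space, ab[1L], ab[2L], label = "outdoor possible")
  tr <- trajectory_record(region, P0, list(P1, P2),
                          discernments = list(G1, discernment_finest(space)),
                          data = list("forecast", c("forecast", "prophet")))
  x0_in <- region$contains(x0) > 0
  tr$prediction_prob <- if (x0_in) tr$P_A else 1 - tr$P_A
  tr$delta <- delta
  tr
}

#' Study replication experiment
#'
#' Two laboratories estimate a prevalence; the proposition is that the
#' second study replicates the first within tolerance `eps`
#' (`A = {|x2 - x1| <= eps}` on `X = [0, 1]^2`).  With full information
#' transfer the informed measure is the point mass at the true pair, so
#' the replication probability is the indicator `1(|x02 - x01| <= eps)`.
#' With partial transfer the second prevalence is only discernible with
#' precision `delta`; under screening the replication probability becomes
#' the overlap `N |R_j0 \cap [x01 - eps, x01 + eps]|` of the quantisation
#' cell containing the true second prevalence with the tolerance interval.
#' A general partial case integrates the overlap against a user-supplied
#' informed measure on the square.
#'
#' @param delta Quantisation precision `1/N` of the partially informed
#'   study.
#' @param eps Replication tolerance in `(0, 1)`.
#' @param x01,x02 True prevalences of the two studies.
#' @param info `"full"` or `"partial"`.
#' @param P2 Optional informed [belief_measure()] on `[0,1]^2` for the
#'   general partial case (grid aligned with `delta` in dimension 2);
#'   when absent the screening closed form is used.
#' @return List of class `replication_result`: `P0_A`, `P_A` (the
#'   step's replication probability), `I_plus`, `j0` (partial case),
#'   `x0_in_A`, and `weak_learning`.
#' @export
replication_experiment <- function(delta = 0.1, eps = 0.04,
                                   x01 = 0.55, x02 = 0.55,
                                   info = c("partial", "full"), P2 = NULL) {
  info <- match.arg(info)
  stopifnot(eps > 0, eps < 1)
  P0_A <- 2 * eps - eps^2
  x0_in <- abs(x02 - x01) <= eps
  if (info == "full") {
    P_A <- as.numeric(x0_in)
    j0 <- NA_integer_
  } else {
    N <- round(1 / delta)
    if (abs(N * delta - 1) > 1e-9)
      stop("delta must be 1/N for an integer N", call. = FALSE)
    if (is.null(P2)) {
      j0 <- min(floor(x02 / delta) + 1L, N)
      lo <- (j0 - 1L) * delta; hi <- j0 * delta
      P_A <- N * max(0, min(hi, x01 + eps) - max(lo, x01 - eps))
    } else {
      stopifnot(inherits(P2, "belief_measure"), P2$space$kind == "box",
                P2$space$q == 2L)
      step2 <- P2$space$resolution[2L] / N
      if (abs(step2 - round(step2)) > 1e-9)
        stop("P2 grid must align with delta in dimension 2", call. = FALSE)
      ctr <- cell_centers(P2$space)
      j <- pmin(floor(ctr[, 2L] / delta) + 1L, N)
      lo <- (j - 1L) * delta; hi <- j * delta
      overlap <- pmax(0, pmin(hi, ctr[, 1L] + eps) -
                        pmax(lo, ctr[, 1L] - eps))
      P_A <- sum(P2$mass * N * overlap)
      if (!is.null(P2$atoms)) {
        for (i in seq_along(P2$atoms$x)) {
          pt <- P2$atoms$x[[i]]
          ja <- min(floor(pt[2L] / delta) + 1L, N)
          ov <- max(0, min(ja * delta, pt[1L] + eps) -
                      max((ja - 1L) * delta, pt[1L] - eps))
          P_A <- P_A + P2$atoms$w[i] * N * ov
        }
      }
      j0 <- min(floor(x02 / delta) + 1L, N)
    }
  }
  I_plus <- if (P_A > 0) log(P_A / P0_A) else -Inf
  weak <- if (x0_in) I_plus > .tau else I_plus < -.tau
  structure(list(P0_A = P0_A, P_A = P_A, I_plus = I_plus, j0 = j0,
                 x0_in_A = x0_in, weak_learning = weak,
                 delta = delta, eps = eps, info = info),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Replication probability P(A) = %.4g (baseline %.4g), I+ = %s\n",
              x$P_A, x$P0_A, format(x$I_plus, digits = 4L)))
  cat("weak learning:", x$weak_learning, "\n")
  invisible(x)
}

#' Causal model with binary exposure and confounders
#'
#' Worlds are binary vectors `(x1, ..., xn)`: an exposure, `n - 2`
#' confounders, and the outcome `xn` (symptom status).  The outcome
#' probability given the covariates follows a logistic regression with
#' known coefficients; covariates are independent Bernoulli by default.
#'
#' @param beta Regression coefficients `(b0, ..., b_{n-1})`.
#' @param x0 The true world: the individual's covariate/outcome vector,
#'   length `n = length(beta)`.
#' @param cov_probs Marginal success probabilities of the `n - 1`
#'   covariates (default all 0.5).
#' @return List of class `causal_model`.
#' @export
causal_model <- function(beta, x0, cov_probs = NULL) {
  n <- length(x0)
  stopifnot(n >= 2L, length(beta) == n, all(x0 %in% c(0, 1)))
  if (n > 20L)
    stop("unsupported size: exact enumeration needs n <= 20", call. = FALSE)
  cov_probs <- cov_probs %||% rep(0.5, n - 1L)
  stopifnot(length(cov_probs) == n - 1L,
            all(cov_probs > 0 & cov_probs < 1))
  structure(list(beta = beta, x0 = as.integer(x0), n = n,
                 cov_probs = cov_probs),
            class = "causal_model")
}

#' Unmeasured confounding experiment
#'
#' Sequentially revealing an individual's covariates sharpens the
#' prediction of their outcome: after `k` covariates the belief in the
#' outcome proposition `A = {x : xn = 1}` is the conditional outcome
#' probability `g_k(x01..x0k)` under the population distribution, reaching
#' the individual's actual status (full knowledge) at `k = n`.  Under
#' conditional exchangeability the counterfactual probability
#' `h_k` — the outcome probability had the first `k` covariates been set
#' rather than observed — is computed by marginalising the remaining
#' covariates; with independent covariates the two coincide.  Everything
#' is computed by exact enumeration of the covariate patterns.
#'
#' @param model A [causal_model()].
#' @param k_max Build the measure trajectory up to this step (default
#'   `n`); the table always covers all steps.
#' @param with_trajectory Also build the finite-space trajectory of
#'   conditional measures (Hamming metric), for the sequential verdicts.
#' @return List of class `confounding_experiment` with the step table
#'   (`k`, `g_k`, `h_k`, `P_A`, `weak_learning`), the prevalence `P0_A`,
#'   the logged observed and counterfactual risk-ratio decompositions, and
#'   (optionally) `trajectory`.
#' @export
confounding_experiment <- function(model, k_max = model$n,
                                   with_trajectory = model$n <= 12L) {
  n <- model$n
  beta <- model$beta
  x0 <- model$x0
  pats <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n - 1L),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(pats) <- NULL
  g <- stats::plogis(beta[1L] + pats %*% beta[-1L])[, 1L]
  wts <- apply(pats, 1L, function(r)
    prod(ifelse(r == 1L, model$cov_probs, 1 - model$cov_probs)))
  P0_A <- sum(wts * g)
  cond_g <- function(k) {
    if (k == 0L) return(P0_A)
    keep <- rowSums(pats[, seq_len(k), drop = FALSE] ==
                      matrix(x0[seq_len(k)], nrow(pats), k, byrow = TRUE)) == k
    sum(wts[keep] * g[keep]) / sum(wts[keep])
  }
  counterfactual_h <- function(k) {
    if (k == 0L) return(P0_A)
    fixed <- pats
    fixed[, seq_len(k)] <- matrix(x0[seq_len(k)], nrow(pats), k, byrow = TRUE)
    gs <- stats::plogis(beta[1L] + fixed %*% beta[-1L])[, 1L]
    if (k == n - 1L) return(gs[1L])
    rest <- (k + 1L):(n - 1L)
    w_rest <- apply(pats[, rest, drop = FALSE], 1L, function(r)
      prod(ifelse(r == 1L, model$cov_probs[rest], 1 - model$cov_probs[rest])))
    sum(w_rest * gs) / sum(w_rest)
  }
  ks <- 0:n
  g_k <- c(vapply(0:(n - 1L), cond_g, 1), NA)
  h_k <- c(vapply(0:(n - 1L), counterfactual_h, 1), NA)
  P_A <- c(g_k[seq_len(n)], x0[n])
  weak <- if (x0[n] == 1L) P_A > P0_A + .tau else P_A < P0_A - .tau
  g1 <- function(v) { xx <- x0; xx[1L] <- v
    keep <- pats[, 1L] == v
    sum(wts[keep] * g[keep]) / sum(wts[keep]) }
  h1 <- function(v) { fixed <- pats; fixed[, 1L] <- v
    gs <- stats::plogis(beta[1L] + fixed %*% beta[-1L])[, 1L]
    if (n == 2L) return(gs[1L])
    rest <- 2:(n - 1L)
    w_rest <- apply(pats[, rest, drop = FALSE], 1L, function(r)
      prod(ifelse(r == 1L, model$cov_probs[rest], 1 - model$cov_probs[rest])))
    sum(w_rest * gs) / sum(w_rest) }
  ain1 <- function(p) log(p / P0_A)
  out <- list(
    table = data.frame(k = ks, g_k = g_k, h_k = h_k, P_A = P_A,
                       weak_learning = weak),
    P0_A = P0_A,
    I1_exposed = ain1(g1(1L)), I1_unexposed = ain1(g1(0L)),
    I1_tilde_exposed = ain1(h1(1L)), I1_tilde_unexposed = ain1(h1(0L)),
    log_risk_ratio = ain1(g1(1L)) - ain1(g1(0L)),
    log_causal_risk_ratio = ain1(h1(1L)) - ain1(h1(0L)),
    model = model)
  if (with_trajectory) {
    labels <- apply(rbind(cbind(pats, 0L), cbind(pats, 1L)), 1L,
                    paste, collapse = "")
    coords <- rbind(cbind(pats, 0L), cbind(pats, 1L))
    rownames(coords) <- labels
    space <- world_space(points = labels, x0 = paste(x0, collapse = ""),
                         coords = coords)
    p0_mass <- c(wts * (1 - g), wts * g)
    P0m <- belief_measure(space, mass = p0_mass)
    cond_measure <- function(k) {
      if (k == 0L) return(P0m)
      match_k <- rowSums(coords[, seq_len(k), drop = FALSE] ==
                           matrix(x0[seq_len(k)], nrow(coords), k,
                                  byrow = TRUE)) == k
      belief_measure(space, mass = p0_mass * match_k)
    }
    measures <- lapply(seq_len(min(k_max, n)), cond_measure)
    region <- truth_region(space,
                           predicate = function(lbl)
                             substr(lbl, n, n) == "1",
                           label = "has symptoms")
    disc <- lapply(seq_len(min(k_max, n)), function(k)
      discernment(space, assignment = apply(
        coords[, seq_len(k), drop = FALSE], 1L, paste, collapse = "") |>
          (\(v) match(v, unique(v)))()))
    out$trajectory <- trajectory_record(region, P0m, measures,
                                        metric = world_metric("hamming"),
                                        discernments = disc,
                                        data = lapply(seq_along(measures),
                                                      function(k) x0[seq_len(k)]))
    out$space <- space
  }
  structure(out, class = "confounding_experiment")
}

#' @export
print.confounding_experiment <- function(x, ...) {
  cat(sprintf("Confounding experiment, n = %d; prevalence P0(A) = %.4g\n",
              x$model$n, x$P0_A))
  print(x$table)
  cat(sprintf("log risk ratio %.4g (observed), %.4g (counterfactual)\n",
              x$log_risk_ratio, x$log_causal_risk_ratio))
  invisible(x)
}
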