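# Strictness margin for all strict inequalities in the verdict
# definitions: equality within tau counts as non-strict, avoiding
# floating-point false positives.
.tau <- 1e-9

new_verdict <- function(kind, scope, mode, outcome, evidence = list(),
                        diagnostic = FALSE) {
  structure(list(kind = kind, scope = scope, mode = mode,
                 outcome = isTRUE(outcome), evidence = evidence,
                 diagnostic = diagnostic),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("%s%s verdict (%s, %s): %s\n",
              if (x$diagnostic) "diagnostic " else "",
              x$kind, x$scope, x$mode,
              if (x$outcome) "YES" else "no"))
  for (nm in names(x$evidence)) {
    v <- x$evidence[[nm]]
    if (is.numeric(v) && length(v) == 1L)
      cat(sprintf("  %s = %s\n", nm, format(v, digits = 6L)))
    else if (is.logical(v) && length(v) == 1L)
      cat(sprintf("  %s: %s\n", nm, v))
  }
  invisible(x)
}

#' Static learning verdict
#'
#' Learning about the proposition has occurred when the agent's belief
#' moved in the true direction relative to the ignorance baseline:
#' `I+(A) > 0` when the true world lies in `A`, or `I+(A) < 0` when it
#' does not.  Full learning is the extreme: `I+(A) = -log P0(A)` (i.e.
#' `P(A) = 1`) when the proposition is true, or `I+(A) = -Inf`
#' (`P(A) = 0`) when it is false.  In expected mode the same inequalities
#' are evaluated for the expected posterior, supplied directly or built
#' from a model via [expected_posterior()].
#'
#' @param P The agent's [belief_measure()] (or expected posterior).
#' @param P0 The baseline [belief_measure()].
#' @param region The proposition's [truth_region()]; `P0(A)` must lie
#'   strictly between 0 and 1.
#' @param mode `"conditional"` (observed data) or `"expected"`.
#' @param model,seed,reps Optional: in expected mode with a model given,
#'   `P` is replaced by `expected_posterior(P, model, ...)`.
#' @param tau Strictness margin.
#' @return A `verdict` with `evidence` holding `I_plus`, `P_A`, `P0_A`,
#'   the full-learning bound and flag, and `x0_in_A`.
#' @export
assess_learning <- function(P, P0, region, mode = c("conditional", "expected"),
                            model = NULL, seed = NULL, reps = 1e4,
                            tau = .tau) {
  mode <- match.arg(mode)
  if (mode == "expected" && !is.null(model)) {
    P <- expected_posterior(P, model,
                            mode = if (!is.null(model$outcomes)) "enumerate"
                                   else "monte_carlo",
                            reps = reps, seed = seed)
  }
  p0 <- region_prob(P0, region)
  if (p0 <= tau || p0 >= 1 - tau)
    stop("undefined learning: P0(A) must lie strictly in (0, 1)",
         call. = FALSE)
  a <- active_info(P, P0, region)
  x0_in <- region$contains(P$space$x0) > 0
  learned <- if (x0_in) a$value > tau else a$value < -tau
  bound <- -log(p0)
  full <- if (x0_in) is.finite(a$value) && abs(a$value - bound) <= tau
          else a$value == -Inf
  new_verdict(if (full) "full_learning" else "learning", "static", mode,
              learned,
              evidence = list(I_plus = a$value, P_A = a$P_A, P0_A = p0,
                              full_bound = bound, full_learning = full,
                              x0_in_A = x0_in))
}

#' Static knowledge-acquisition verdict
#'
#' Knowledge is justified true belief: learning must have occurred
#' ([assess_learning()]), and in addition the posterior must be at least
#' as concentrated around the true world as the baseline on every closed
#' ball — `P(B_eps(x0)) > 0` and `P(B_eps(x0)) >= P0(B_eps(x0))` for all
#' radii on the evaluation grid, with strict inequality at one or more
#' radii.  Full knowledge requires the point mass at the true world.
#'
#' @inheritParams assess_learning
#' @param metric A [world_metric()].
#' @param eps_grid Radii at which the ball conditions are checked
#'   (defaults to [epsilon_grid()]).
#' @return A `verdict`; `evidence$balls` is a data frame of
#'   `(eps, P_ball, P0_ball)`.
#' @export
assess_knowledge <- function(P, P0, metric = default_metric(P$space), region,
                             eps_grid = NULL,
                             mode = c("conditional", "expected"),
                             model = NULL, seed = NULL, reps = 1e4,
                             tau = .tau) {
  mode <- match.arg(mode)
  if (mode == "expected" && !is.null(model)) {
    P <- expected_posterior(P, model,
                            mode = if (!is.null(model$outcomes)) "enumerate"
                                   else "monte_carlo",
                            reps = reps, seed = seed)
  }
  space <- P$space
  if (is.null(eps_grid)) eps_grid <- epsilon_grid(space, metric)
  if (length(eps_grid) == 0L) stop("empty eps grid", call. = FALSE)
  learn <- assess_learning(P, P0, region, mode = "conditional", tau = tau)
  balls <- lapply(eps_grid, function(e) ball(space, metric, e))
  pb <- vapply(balls, function(b) region_prob(P, b), 1)
  pb0 <- vapply(balls, function(b) region_prob(P0, b), 1)
  positive <- all(pb > tau)
  dominate <- all(pb >= pb0 - tau)
  strict <- any(pb > pb0 + tau)
  full <- is_point_mass_at_x0(P, tau)
  know <- learn$outcome && positive && dominate && strict
  new_verdict(if (full && know) "full_knowledge" else "knowledge",
              "static", mode, know,
              evidence = c(learn$evidence,
                           list(balls = data.frame(eps = eps_grid,
                                                   P_ball = pb,
                                                   P0_ball = pb0),
                                ball_positive = positive,
                                ball_dominates = dominate,
                                ball_strict = strict,
                                full_knowledge = full && know)))
}

is_point_mass_at_x0 <- function(P, tau = .tau) {
  space <- P$space
  if (space$kind == "finite")
    return(abs(P$mass[cell_index(space, space$x0)] - 1) <= tau)
  if (is.null(P$atoms)) return(FALSE)
  at_x0 <- vapply(P$atoms$x, function(a)
    isTRUE(all.equal(as.numeric(a), as.numeric(space$x0))), TRUE)
  sum(P$atoms$w[at_x0]) >= 1 - tau
}

#' Trajectory of a discernment and data collection process
#'
#' Records an agent's belief sequence `P1, ..., Pn` over nested
#' discernments and growing data sets, with everything the sequential and
#' asymptotic verdicts need precomputed: `Pk(A)`, `Ik+`, and ball
#' probabilities over the radius grid.  Built either from explicit
#' measures or (for long conjugate runs) from closed-form step summaries
#' via [trajectory_from_values()].
#'
#' @param region The proposition's [truth_region()].
#' @param P0 The baseline [belief_measure()].
#' @param measures List of step measures `P1, ..., Pn`.
#' @param metric A [world_metric()].
#' @param eps_grid Ball radii (defaults to [epsilon_grid()]).
#' @param discernments Optional list of per-step [discernment()]s; must be
#'   nested (each a refinement of its predecessor).
#' @param data Optional list of per-step data descriptors.
#' @param k Step indices (defaults to `1:n`).
#' @param nested_data Logical construction flag: are the data sets nested?
#' @return An object of class `trajectory_record`.
#' @export
trajectory_record <- function(region, P0, measures,
                              metric = default_metric(P0$space),
                              eps_grid = NULL, discernments = NULL,
                              data = NULL, k = NULL, nested_data = TRUE) {
  space <- P0$space
  if (is.null(eps_grid)) eps_grid <- epsilon_grid(space, metric)
  n <- length(measures)
  if (n < 1L) stop("trajectory needs at least one step", call. = FALSE)
  if (!is.null(discernments) && length(discernments) > 1L) {
    for (i in seq_len(length(discernments) - 1L)) {
      if (!is_refinement(discernments[[i + 1L]], discernments[[i]]))
        stop("invalid trajectory: discernments are not nested",
             call. = FALSE)
    }
  }
  balls <- lapply(eps_grid, function(e) ball(space, metric, e))
  ball_mat <- t(vapply(measures, function(m)
    vapply(balls, function(b) region_prob(m, b), 1),
    numeric(length(balls))))
  P_A <- vapply(measures, function(m) region_prob(m, region), 1)
  P0_A <- region_prob(P0, region)
  ball0 <- vapply(balls, function(b) region_prob(P0, b), 1)
  structure(list(space = space, region = region, metric = metric,
                 eps_grid = eps_grid, k = k %||% seq_len(n),
                 P_A = P_A, P0_A = P0_A,
                 I_plus = ifelse(P_A > 0, log(P_A / P0_A), -Inf),
                 ball = ball_mat, ball0 = ball0,
                 x0_in = region$contains(space$x0) > 0,
                 measures = measures, P0 = P0,
                 discernments = discernments, data = data,
                 nested_data = nested_data),
            class = "trajectory_record")
}

#' @rdname trajectory_record
#' @param P_A,ball,ball0 Precomputed step summaries: `Pk(A)` per step, the
#'   step-by-radius ball probability matrix, and the baseline ball
#'   probabilities.
#' @param P0_A Baseline probability of `A`.
#' @param space The [world_space()].
#' @param x0_in Logical: does the true world satisfy the proposition?
#' @export
trajectory_from_values <- function(space, region, k, P_A, P0_A, ball, ball0,
                                   eps_grid, x0_in = region$contains(space$x0) > 0,
                                   metric = default_metric(space),
                                   nested_data = TRUE) {
  stopifnot(length(P_A) == length(k), nrow(ball) == length(k),
            ncol(ball) == length(eps_grid), length(ball0) == length(eps_grid))
  structure(list(space = space, region = region, metric = metric,
                 eps_grid = eps_grid, k = k, P_A = P_A, P0_A = P0_A,
                 I_plus = ifelse(P_A > 0, log(P_A / P0_A), -Inf),
                 ball = ball, ball0 = ball0, x0_in = x0_in,
                 measures = NULL, P0 = NULL, discernments = NULL,
                 data = NULL, nested_data = nested_data),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("Trajectory of %d steps on a %s space; P0(A) = %.4g\n",
              length(x$k), x$space$kind, x$P0_A))
  print(utils::head(data.frame(k = x$k, P_A = x$P_A, I_plus = x$I_plus), 8L))
  invisible(x)
}

#' Tabulate a trajectory
#'
#' @param x A [trajectory_record()].
#' @param ... Unused.
#' @return Data frame with step index, `Pk(A)`, `Ik+` and one column per
#'   ball radius.
#' @export
as.data.frame.trajectory_record <- function(x, ...) {
  bcols <- as.data.frame(x$ball)
  names(bcols) <- sprintf("P_ball_eps_%g", x$eps_grid)
  cbind(data.frame(k = x$k, Pk_A = x$P_A, Ik_plus = x$I_plus), bcols)
}

chain_monotone <- function(v, up = TRUE, tau = .tau) {
  d <- diff(v)
  if (up) list(ok = all(d >= -tau), strict = any(d > tau))
  else list(ok = all(d <= tau), strict = any(d < -tau))
}

#' Strong sequential verdict
#'
#' A learning process in the strong sense: the active-information sequence
#' is monotone in the true direction at every step, starting from the
#' baseline's 0 — non-decreasing `0 <= I1+ <= ... <= In+` when the
#' proposition is true, non-increasing when false — with at least one
#' strict step.  Strong knowledge acquisition additionally requires the
#' ball chain `P0(B_eps) <= P1(B_eps) <= ... <= Pn(B_eps)` at every grid
#' radius with `P1(B_eps) > 0`, strict for at least one (step, radius)
#' pair.
#'
#' @param trajectory A [trajectory_record()].
#' @param with_knowledge Also evaluate the strong knowledge conditions.
#' @param mode Label only (`"conditional"` or `"expected"`; for expected
#'   verdicts build the trajectory from expected posteriors).
#' @param tau Strictness margin.
#' @return A `verdict`.
#' @export
assess_strong <- function(trajectory, with_knowledge = TRUE,
                          mode = c("conditional", "expected"), tau = .tau) {
  mode <- match.arg(mode)
  tr <- trajectory
  chain <- c(0, tr$I_plus)
  mono <- chain_monotone(chain, up = tr$x0_in, tau = tau)
  learning <- mono$ok && mono$strict
  ev <- list(I_chain = chain, monotone = mono$ok,
             strict_step = mono$strict, x0_in_A = tr$x0_in)
  if (!with_knowledge)
    return(new_verdict("learning", "strong", mode, learning, ev))
  full_chain <- rbind(tr$ball0, tr$ball)
  per_eps <- apply(full_chain, 2L, function(col) {
    m <- chain_monotone(col, up = TRUE, tau = tau)
    c(ok = m$ok, strict = m$strict)
  })
  balls_ok <- all(per_eps["ok", ])
  balls_strict <- any(per_eps["strict", ])
  p1_positive <- all(tr$ball[1L, ] > tau)
  know <- learning && balls_ok && balls_strict && p1_positive
  new_verdict("knowledge", "strong", mode, know,
              c(ev, list(strong_learning = learning,
                         ball_chain_monotone = balls_ok,
                         ball_chain_strict = balls_strict,
                         P1_ball_positive = p1_positive)))
}

#' Weak sequential verdict
#'
#' Learning in the weak sense at step `n`: `In+(A) > 0` when the
#' proposition is true (or `< 0` when false), regardless of the path
#' taken.  Weak knowledge acquisition adds the static ball conditions at
#' step `n`.  At `n = 1` these verdicts coincide with the static ones.
#'
#' @inheritParams assess_strong
#' @param n Step at which to assess (defaults to the last).
#' @param with_knowledge Also evaluate the ball conditions.
#' @return A `verdict`.
#' @export
assess_weak <- function(trajectory, n = length(trajectory$k),
                        with_knowledge = TRUE,
                        mode = c("conditional", "expected"), tau = .tau) {
  mode <- match.arg(mode)
  tr <- trajectory
  i <- match(n, tr$k)
  if (is.na(i)) i <- n
  if (i < 1L || i > length(tr$k)) stop("step outside trajectory",
                                       call. = FALSE)
  I_n <- tr$I_plus[i]
  learning <- if (tr$x0_in) I_n > tau else I_n < -tau
  ev <- list(I_n = I_n, step = tr$k[i], x0_in_A = tr$x0_in)
  if (!with_knowledge)
    return(new_verdict("learning", "weak", mode, learning, ev))
  pb <- tr$ball[i, ]
  pb0 <- tr$ball0
  know <- learning && all(pb > tau) && all(pb >= pb0 - tau) &&
    any(pb > pb0 + tau)
  new_verdict("knowledge", "weak", mode, know,
              c(ev, list(weak_learning = learning,
                         ball_positive = all(pb > tau),
                         ball_dominates = all(pb >= pb0 - tau),
                         ball_strict = any(pb > pb0 + tau))))
}

#' Asymptotic verdict (finite-horizon diagnostic)
#'
#' Estimates the limit-infimum/supremum conditions of asymptotic learning
#' and knowledge acquisition by the minimum/maximum of `Pk(A) / P0(A)`
#' (and of ball-probability ratios) over the trailing fraction of a long
#' trajectory.  The verdict is labelled diagnostic: a finite run can
#' support but never prove a limit.  The full-learning flag reports
#' whether the tail of `Pk(A)` sits within tolerance of its limiting value
#' (1 if the proposition is true, 0 if not); in the false case the
#' limiting active information is the `-Inf` flag.
#'
#' @inheritParams assess_strong
#' @param tail_fraction Fraction of trailing steps used for the tail
#'   estimates.
#' @param tol Tolerance for the full-learning/knowledge tail checks.
#' @return A diagnostic `verdict`.
#' @export
assess_asymptotic <- function(trajectory, tail_fraction = 0.2, tol = 1e-2,
                              tau = .tau) {
  tr <- trajectory
  n <- length(tr$k)
  if (n < 20L) stop("too-short trajectory for asymptotic diagnostics",
                    call. = FALSE)
  tail_idx <- seq.int(max(1L, n - ceiling(tail_fraction * n) + 1L), n)
  ratio <- tr$P_A[tail_idx] / tr$P0_A
  I_liminf <- log(min(ratio))
  I_limsup <- log(max(ratio))
  learning <- if (tr$x0_in) I_liminf > tau else I_limsup < -tau
  converged_to_zero <- all(tr$P_A[tail_idx] <= tol)
  full <- if (tr$x0_in) all(abs(tr$P_A[tail_idx] - 1) <= tol)
          else converged_to_zero
  ball_ratio <- sweep(tr$ball[tail_idx, , drop = FALSE], 2L, tr$ball0, "/")
  liminf_balls <- apply(ball_ratio, 2L, min)
  ball_pos <- apply(tr$ball[tail_idx, , drop = FALSE], 2L, min) > tau
  know <- learning && all(ball_pos) && all(liminf_balls >= 1 - tol) &&
    any(liminf_balls > 1 + tau)
  full_know <- full && all(apply(tr$ball[tail_idx, , drop = FALSE], 2L,
                                 function(col) all(abs(col - 1) <= tol)))
  new_verdict("knowledge", "asymptotic", "conditional", know,
              evidence = list(I_liminf = I_liminf, I_limsup = I_limsup,
                              I_lim_minus_inf = converged_to_zero,
                              asymptotic_learning = learning,
                              full_learning = full,
                              full_knowledge = full_know,
                              tail_steps = length(tail_idx),
                              x0_in_A = tr$x0_in),
              diagnostic = TRUE)
}

#' Conjugate Bernoulli family for contraction diagnostics
#'
#' Independent coin tosses with a uniform (Beta) prior: sufficient
#' statistic `m` successes out of `k`, maximum-likelihood estimate `m/k`,
#' one posterior draw from `Beta(1 + m, 1 + k - m)` and Fisher information
#' `1 / (x0 (1 - x0))`.
#'
#' @return An iid family object for [contraction_diagnostics()].
#' @export
bernoulli_family <- function() {
  structure(list(
    iid = TRUE,
    sample_suff = function(n, k, x0) stats::rbinom(n, k, x0),
    mle = function(m, k) m / k,
    posterior_draw = function(m, k) stats::rbeta(length(m), 1 + m, 1 + k - m),
    fisher = function(x0) 1 / (x0 * (1 - x0))
  ), class = "iid_family")
}

#' Posterior-contraction diagnostics
#'
#' Simulation check of the asymptotic behaviour of posterior draws around
#' the true world for iid data: the posterior contracts at rate
#' `1/sqrt(k)`, and a single posterior draw per data set has limiting
#' variance twice the inverse Fisher information (the Bernstein-von Mises
#' normal around the maximum-likelihood estimate convolved with the
#' sampling normal of that estimate).  Reports the fitted exponent of the
#' median absolute error against `k` (expected near -1/2), the variance
#' ratio `Var(sqrt(k) (Xk - x0)) * J(x0)` at the largest `k` (expected
#' near 2), and the analogous maximum-likelihood ratio (expected near 1).
#' One posterior draw per simulated data set is used, matching the
#' compound limiting distribution.
#'
#' @param family An iid family object such as [bernoulli_family()].
#' @param x0 True parameter value.
#' @param k_grid Increasing sample sizes.
#' @param replicates Data sets simulated per sample size.
#' @param seed Integer seed (mandatory).
#' @return An object of class `contraction_diagnostics`: a per-`k` table
#'   plus `exponent`, `var_ratio`, `mle_var_ratio`, `fisher`.
#' @export
contraction_diagnostics <- function(family = bernoulli_family(), x0,
                                    k_grid = c(100L, 400L, 1600L, 6400L),
                                    replicates = 2000L, seed) {
  if (!inherits(family, "iid_family") || !isTRUE(family$iid))
    stop("unsupported model: contraction diagnostics need an iid family",
         call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  k_grid <- sort(as.integer(k_grid))
  J <- family$fisher(x0)
  rows <- lapply(k_grid, function(k) {
    m <- family$sample_suff(replicates, k, x0)
    mle <- family$mle(m, k)
    xk <- family$posterior_draw(m, k)
    data.frame(k = k,
               median_abs_err = stats::median(abs(xk - x0)),
               median_sq_err = stats::median((xk - x0)^2),
               var_scaled = stats::var(sqrt(k) * (xk - x0)),
               var_scaled_mle = stats::var(sqrt(k) * (mle - x0)))
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(log(median_abs_err) ~ log(k), data = tab)
  structure(list(table = tab,
                 exponent = unname(stats::coef(fit)[2L]),
                 var_ratio = tab$var_scaled[nrow(tab)] * J,
                 mle_var_ratio = tab$var_scaled_mle[nrow(tab)] * J,
                 fisher = J, replicates = replicates, seed = seed),
            class = "contraction_diagnostics")
}

#' @export
print.contraction_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("Contraction diagnostics (%d replicates):\n",
                     "  fitted rate exponent %.3f (expect -0.5)\n",
                     "  posterior-draw variance ratio %.3f (expect 2)\n",
                     "  ML-estimator variance ratio %.3f (expect 1)\n"),
              x$replicates, x$exponent, x$var_ratio, x$mle_var_ratio))
  invisible(x)
}

#' Distance-based knowledge verdict
#'
#' Alternative justification criterion: the agent has acquired knowledge
#' if learning occurred and the belief is closer than the baseline to the
#' oracle's point mass at the true world, `d(P, delta_x0) < d(P0,
#' delta_x0)`.  With the Kullback-Leibler distance this reduces to
#' `P(x0 cell) > P0(x0 cell)` (distance `-log P(x0)`); the one-dimensional
#' Wasserstein distance to a point mass is the mean absolute deviation
#' from `x0`, computed exactly for piecewise-constant densities.
#'
#' @inheritParams assess_learning
#' @param distance_kind `"kl"` or `"wasserstein_1d"`.
#' @return A `verdict` with the two distances in the evidence; an
#'   infinite KL distance (zero mass at the true world) yields a false
#'   verdict with an `infinite_distance` flag.
#' @export
distance_knowledge <- function(P, P0, region,
                               distance_kind = c("kl", "wasserstein_1d"),
                               tau = .tau) {
  distance_kind <- match.arg(distance_kind)
  space <- P$space
  learn <- assess_learning(P, P0, region, tau = tau)
  if (distance_kind == "kl") {
    d_p <- kl_point_distance(P)
    d_p0 <- kl_point_distance(P0)
  } else {
    if (space$kind != "box" || space$q != 1L)
      stop("wasserstein_1d needs a one-dimensional box space", call. = FALSE)
    d_p <- mean_abs_dev(P)
    d_p0 <- mean_abs_dev(P0)
  }
  know <- learn$outcome && is.finite(d_p) && d_p < d_p0 - tau
  new_verdict("knowledge", "static", "conditional", know,
              evidence = list(distance_P = d_p, distance_P0 = d_p0,
                              distance_kind = distance_kind,
                              learned = learn$outcome,
                              infinite_distance = !is.finite(d_p)))
}

# KL distance to the point mass at x0: -log P(x0) (finite) or
# -log P(x0-cell mass + atom weight at x0) on grids.
kl_point_distance <- function(P) {
  space <- P$space
  p <- P$mass[cell_index(space, space$x0)]
  if (!is.null(P$atoms)) {
    at <- vapply(P$atoms$x, function(a)
      isTRUE(all.equal(as.numeric(a), as.numeric(space$x0))), TRUE)
    p <- p + sum(P$atoms$w[at])
  }
  if (p <= 0) Inf else -log(p)
}

# Exact E|X - x0| for a piecewise-constant 1-D measure with atoms.
mean_abs_dev <- function(P) {
  space <- P$space
  x0 <- space$x0
  w <- cell_widths(space)
  lo <- space$bounds[1L, 1L] + (seq_len(space$resolution) - 1L) * w
  hi <- lo + w
  seg <- vapply(seq_along(lo), function(i) {
    l <- lo[i]; u <- hi[i]
    if (x0 <= l) (l + u) / 2 - x0
    else if (x0 >= u) x0 - (l + u) / 2
    else ((x0 - l)^2 + (u - x0)^2) / (2 * (u - l))
  }, 1)
  out <- sum(P$mass * seg)
  if (!is.null(P$atoms))
    out <- out + sum(P$atoms$w *
                       vapply(P$atoms$x, function(a) abs(a - x0), 1))
  out
}
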