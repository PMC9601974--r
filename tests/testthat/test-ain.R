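test_that("active information matches direct arithmetic and its extremes", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  A <- sm$region_scores_well
  P1 <- posterior_update(P0, sm$score_model, 7L)
  a <- active_info(P1, P0, A)
  o <- student_posterior_oracle(7L)
  expect_equal(a$value, log((o[2] + o[3]) / (2 / 3)), tolerance = 1e-12)
  expect_gt(a$value, 0)

  expect_equal(active_info(P0, P0, A)$value, 0)

  # a correct-proposition-excluding measure has I+ = -Inf when S is true
  Pexc <- support_excluding(P0, region = A, kind = "correct_proposition")
  expect_identical(active_info(Pexc, P0, A)$value, -Inf)

  empty <- truth_region(sm$space, points = character(0))
  expect_error(active_info(P1, P0, empty), "P0\\(A\\) = 0")

  # base-2 switch
  expect_equal(active_info(P1, P0, A, base = 2)$value,
               a$value / log(2), tolerance = 1e-12)
})

test_that("active information never exceeds the functional information", {
  set.seed(7)
  for (i in 1:30) {
    sp <- random_finite_space(sample(2:9, 1L))
    P0 <- random_pmf(sp)
    P <- random_pmf(sp)
    pts <- sample(sp$points, sample(seq_along(sp$points), 1L))
    A <- truth_region(sp, points = pts)
    if (region_prob(P0, A) <= 0) next
    expect_lte(active_info(P, P0, A)$value,
               functional_information(P0, A) + 1e-12)
  }
  sp <- three_world_space()
  P0 <- uniform_prior(sp)
  A <- truth_region(sp, points = c("x2", "x3"))
  expect_equal(functional_information(P0, A), log(3 / 2))
  expect_equal(functional_information(P0, truth_region(sp, predicate =
                                                         function(x) TRUE)), 0)
})

test_that("the threshold test rejects at and below the threshold", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  A <- sm$region_scores_well
  P1 <- posterior_update(P0, sm$score_model, 7L)
  a <- active_info(P1, P0, A)
  spec <- test_spec(A, P0 = P0, p = 0.5)      # reject when P(A) <= 0.5
  expect_identical(ain_test(a, spec), "retain_H0")
  expect_identical(ain_test(a, test_spec(A, threshold = -Inf)), "retain_H0")
  expect_identical(ain_test(-Inf, spec), "reject_H0")
  expect_identical(ain_test(a$value, test_spec(A, threshold = a$value)),
                   "reject_H0")  # exact equality rejects
})

test_that("AIN threshold test is equivalent to the posterior-odds rule", {
  set.seed(13)
  for (i in 1:30) {
    sp <- random_finite_space(sample(2:8, 1L))
    P0 <- random_pmf(sp)
    P <- random_pmf(sp)
    pts <- sample(sp$points, sample(seq_along(sp$points), 1L))
    A <- truth_region(sp, points = pts)
    if (region_prob(P0, A) <= 0 || region_prob(P, A) <= 0) next
    r <- stats::rexp(1)
    spec <- test_spec(A, P0 = P0, odds = r)
    freq <- ain_test(active_info(P, P0, A), spec)
    bayes <- if (posterior_odds(P, P0, A)$odds >= r) "reject_H0"
             else "retain_H0"
    expect_identical(freq, bayes)
  }
})

test_that("error rates enumerate exactly and match Monte Carlo", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  spec <- test_spec(sm$region_scores_well, P0 = P0, p = 0.5)

  er <- error_rates(sm$score_model, P0, spec)
  # oracle: P1(A|d) <= 1/2 iff 2 L(d|x2) <= L(d|x1), i.e. d <= 6
  reject_d <- which(2 * stats::dbinom(0:10, 10, 0.8) <=
                      stats::dbinom(0:10, 10, 0.5)) - 1L
  expect_equal(er$alpha, sum(stats::dbinom(reject_d, 10, 0.8)),
               tolerance = 1e-12)

  # threshold below the minimum attainable AIN: never reject
  low <- test_spec(sm$region_scores_well, threshold = -20)
  expect_equal(error_rates(sm$score_model, P0, low)$alpha, 0)

  reps <- 2e4
  erm <- error_rates(sm$score_model, P0, spec, method = "monte_carlo",
                     reps = reps, seed = 3)
  se <- sqrt(er$alpha * (1 - er$alpha) / reps)
  expect_lt(abs(erm$alpha - er$alpha), 3 * se)
  expect_error(error_rates(sm$score_model, P0, spec,
                           method = "monte_carlo"), "seed")

  # beta side: true world outside A
  smf <- student_model(x0 = "x1")
  specf <- test_spec(smf$region_scores_well, P0 = P0, p = 0.5)
  erb <- error_rates(smf$score_model, uniform_prior(smf$space), specf)
  retain_d <- setdiff(0:10, reject_d)
  expect_equal(erb$beta, sum(stats::dbinom(retain_d, 10, 0.5)),
               tolerance = 1e-12)
})

test_that("posterior odds factor into prior odds and Bayes factor", {
  sp <- three_world_space()
  P <- belief_measure(sp, mass = c(1, 1, 1) / 3)
  A2 <- truth_region(sp, points = c("x2", "x3"))
  po <- posterior_odds(P, P, A2)
  expect_equal(po$bayes_factor, 1)

  # P(A) = 2/3 against a baseline with P0(A) = 1/2
  sp4 <- world_space(points = c("a", "b", "c", "d"), x0 = "a")
  A4 <- truth_region(sp4, points = c("a", "b"))
  P4 <- belief_measure(sp4, mass = c(1, 1, 0.5, 0.5) / 3)
  po4 <- posterior_odds(P4, uniform_prior(sp4), A4)
  expect_equal(po4$odds, 0.5, tolerance = 1e-12)
  expect_equal(po4$prior_odds, 1)
  expect_equal(po4$bayes_factor, 0.5, tolerance = 1e-12)

  # consistency with AIN: I+ = -log[P0(A)(1 + odds)]
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  P1 <- posterior_update(P0, sm$score_model, 7L)
  po1 <- posterior_odds(P1, P0, sm$region_scores_well)
  expect_equal(-log((2 / 3) * (1 + po1$odds)),
               active_info(P1, P0, sm$region_scores_well)$value,
               tolerance = 1e-12)

  Pz <- belief_measure(sp, mass = c(1, 0, 0))
  expect_true(posterior_odds(Pz, uniform_prior(sp), A2)$infinite_odds)
})

test_that("KL form is non-negative and equals cross entropy minus entropy", {
  sp <- three_world_space()
  P0 <- uniform_prior(sp)
  expect_equal(kl_ain(P0, P0), 0)
  P <- belief_measure(sp, mass = c(0.5, 0.5, 0))
  expect_equal(kl_ain(P, P0), log(1.5), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:10) {
    spc <- random_finite_space(sample(2:8, 1L))
    P <- random_pmf(spc); Q <- random_pmf(spc)
    # independent oracle: H(P, Q) - H(P)
    ce <- -sum(P$mass * log(Q$mass))
    en <- -sum(P$mass[P$mass > 0] * log(P$mass[P$mass > 0]))
    expect_equal(kl_ain(P, Q), ce - en, tolerance = 1e-9)
    expect_gte(kl_ain(P, Q), 0)
  }
  Q0 <- belief_measure(sp, mass = c(1, 1, 0) / 2)
  expect_identical(kl_ain(P0, Q0), Inf)
})

test_that("mutual-information form equals the enumerated double sum", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)

  flat <- likelihood_model(function(d, w) rep(0.5, NROW(w)),
                           outcomes = c(0L, 1L))
  expect_equal(mutual_info_ain(P0, flat), 0)

  mi <- mutual_info_ain(P0, sm$score_model)
  # oracle: double sum over the 3 x 11 outcomes from raw binomials
  pis <- c(0.5, 0.8, 0.8)
  oracle <- 0
  for (d in 0:10) {
    lv <- stats::dbinom(d, 10, pis)
    ld <- mean(lv)
    oracle <- oracle + sum((1 / 3) * lv * log(lv / ld))
  }
  expect_equal(mi, oracle, tolerance = 1e-12)

  # identity: MI equals the expected KL divergence over data draws
  ekl <- sum(vapply(0:10, function(d) {
    ld <- mean(stats::dbinom(d, 10, pis))
    ld * kl_ain(posterior_update(P0, sm$score_model, d), P0)
  }, 1))
  expect_equal(mi, ekl, tolerance = 1e-9)
})

test_that("likelihood-ratio statistic is a grid maximisation over A", {
  cm <- coin_model(100, resolution = 2000)
  A <- region_box(cm$space, 0.4, 0.6)
  # MLE 0.5 lies inside A
  expect_equal(lr_statistic(cm$model, A, 50), 0, tolerance = 1e-9)
  # A = X
  full <- region_box(cm$space, 0, 1)
  expect_equal(lr_statistic(cm$model, full, 80), 0, tolerance = 1e-9)
  # MLE 0.8 outside A: boundary vs MLE closed form
  lam <- lr_statistic(cm$model, A, 80)
  oracle <- -2 * log(stats::dbinom(80, 100, 0.6) /
                       stats::dbinom(80, 100, 0.8))
  expect_equal(lam, oracle, tolerance = 0.1)
  empty <- truth_region(cm$space, frac = rep(0, 2000))
  expect_error(lr_statistic(cm$model, empty, 50), "empty region")
})
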