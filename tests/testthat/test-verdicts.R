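test_that("static learning verdicts follow the sign of I+", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  A <- sm$region_scores_well
  P1 <- posterior_update(P0, sm$score_model, 7L)

  v <- assess_learning(P1, P0, A)
  expect_true(v$outcome)
  expect_gt(v$evidence$I_plus, 0)

  expect_false(assess_learning(P0, P0, A)$outcome)

  # point mass at x0 with x0 in A: full learning at the bound -log P0(A)
  vfull <- assess_learning(point_mass(sm$space), P0, A)
  expect_true(vfull$outcome)
  expect_identical(vfull$kind, "full_learning")
  expect_equal(vfull$evidence$I_plus, log(3 / 2), tolerance = 1e-9)

  whole <- truth_region(sm$space, predicate = function(x) TRUE)
  expect_error(assess_learning(P1, P0, whole), "strictly in")
})

test_that("knowledge requires justified concentration around x0", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  A <- sm$region_scores_well

  # believing A fully while excluding the true world: learning, no knowledge
  Pexc <- belief_measure(sm$space, mass = c(0, 0, 1))  # all mass on x3
  expect_true(assess_learning(Pexc, P0, A)$outcome)
  expect_false(assess_knowledge(Pexc, P0, region = A)$outcome)

  # step 2 of the student process: knowledge about "knows addition"
  tr <- student_experiment(7L, z2 = 0L, proposition = "knows")
  P2 <- tr$posteriors[[2]]
  vk <- assess_knowledge(P2, P0, region = sm$region_knows)
  expect_true(vk$outcome)

  vfull <- assess_knowledge(point_mass(sm$space), P0, region = A)
  expect_true(vfull$outcome)
  expect_identical(vfull$kind, "full_knowledge")

  expect_error(assess_knowledge(P2, P0, region = sm$region_knows,
                                eps_grid = numeric(0)), "eps grid")
})

test_that("learning and knowledge coincide for the singleton truth set", {
  # Remark-7 equivalence, including the KL distance variant
  set.seed(23)
  for (i in 1:30) {
    sp <- random_finite_space(sample(2:8, 1L))
    P0 <- random_pmf(sp)
    P <- random_pmf(sp)
    A0 <- region_a0(sp)
    learn <- assess_learning(P, P0, A0)$outcome
    know <- assess_knowledge(P, P0, world_metric("categorical"), A0)$outcome
    know_kl <- distance_knowledge(P, P0, A0, "kl")$outcome
    expect_identical(learn, know)
    expect_identical(learn, know_kl)
  }
})

test_that("strong verdicts demand monotone chains", {
  # scoring proposition: the helper signal pushes P(A) down
  trA <- student_experiment(7L, z2 = 0L, proposition = "scores_well")
  vA <- assess_strong(trA)
  expect_false(vA$evidence$strong_learning)
  expect_false(vA$outcome)

  # "knows addition": P0(x2) < P1(x2) < P2(x2) gives the strong chain
  trK <- student_experiment(7L, z2 = 0L, proposition = "knows")
  vK <- assess_strong(trK)
  expect_true(vK$evidence$strong_learning)
  expect_true(vK$outcome)

  # constant trajectory: monotone but no strict step
  sp <- three_world_space()
  P0 <- uniform_prior(sp)
  A <- truth_region(sp, points = c("x2", "x3"))
  trC <- trajectory_record(A, P0, list(P0, P0))
  expect_false(assess_strong(trC)$outcome)

  # non-nested discernments are rejected
  G1 <- discernment(sp, cells = list("x1", c("x2", "x3")))
  G2 <- discernment(sp, cells = list(c("x1", "x2"), "x3"))
  expect_error(trajectory_record(A, P0, list(P0, P0),
                                 discernments = list(G1, G2)),
               "not nested")
})

test_that("weak verdicts look only at the final step", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)

  # n = 1: weak coincides with the static verdicts
  tr1 <- student_experiment(7L)
  vw <- assess_weak(tr1, n = 1L)
  vs <- assess_knowledge(tr1$posteriors[[1]], P0,
                         world_metric("categorical"),
                         sm$region_scores_well)
  expect_identical(vw$outcome, vs$outcome)
  expect_identical(vw$evidence$weak_learning,
                   assess_learning(tr1$posteriors[[1]], P0,
                                   sm$region_scores_well)$outcome)

  # long coin run: weak learning at the horizon
  trc <- coin_experiment(k_max = 1000, seed = 2)
  expect_true(assess_weak(trc, n = 1000)$evidence$weak_learning)

  # strong implies weak at the final step
  for (tr in list(student_experiment(7L, z2 = 0L, proposition = "knows"),
                  dating_experiment())) {
    if (assess_strong(tr)$evidence$strong_learning)
      expect_true(assess_weak(tr)$evidence$weak_learning)
  }
})

test_that("full knowledge implies full learning but not conversely", {
  sm <- student_model()
  P0 <- uniform_prior(sm$space)
  A <- sm$region_scores_well
  vk <- assess_knowledge(point_mass(sm$space), P0, region = A)
  vl <- assess_learning(point_mass(sm$space), P0, A)
  expect_identical(vk$kind, "full_knowledge")
  expect_identical(vl$kind, "full_learning")

  # full learning (P(A) = 1) without the true world in support
  Pwrong <- belief_measure(sm$space, mass = c(0, 0, 1))
  vl2 <- assess_learning(Pwrong, P0, A)
  expect_identical(vl2$kind, "full_learning")
  expect_false(assess_knowledge(Pwrong, P0, region = A)$outcome)
})

test_that("asymptotic diagnostics read the trajectory tail", {
  tr <- coin_experiment(x0 = 0.5, eps = 0.1, k_max = 2000, seed = 11)
  va <- assess_asymptotic(tr)
  expect_true(va$diagnostic)
  expect_true(va$evidence$asymptotic_learning)
  expect_true(va$evidence$full_learning)
  expect_true(va$outcome)

  # constant at the baseline: no learning
  sp <- three_world_space()
  P0 <- uniform_prior(sp)
  A <- truth_region(sp, points = c("x2", "x3"))
  trC <- trajectory_record(A, P0, rep(list(P0), 25L))
  expect_false(assess_asymptotic(trC)$evidence$asymptotic_learning)

  # belief drifting into the complement while S is true: the -Inf flag
  ks <- 1:40
  drift <- trajectory_from_values(
    space = tr$space, region = tr$region, k = ks,
    P_A = 0.2 * exp(-ks / 4), P0_A = 0.2,
    ball = matrix(rep(tr$ball0, each = 40) * exp(-ks / 4), nrow = 40),
    ball0 = tr$ball0, eps_grid = tr$eps_grid)
  vd <- assess_asymptotic(drift)
  expect_false(vd$evidence$asymptotic_learning)
  expect_true(vd$evidence$I_lim_minus_inf)

  expect_error(assess_asymptotic(trajectory_record(A, P0, list(P0))),
               "too-short")
})

test_that("posterior draws contract at rate 1/sqrt(k) with variance 2/J", {
  cd <- contraction_diagnostics(x0 = 0.5, k_grid = c(250, 500, 1000, 2000),
                                replicates = 1500, seed = 19)
  expect_equal(cd$exponent, -0.5, tolerance = 0.1)
  expect_equal(cd$mle_var_ratio, 1, tolerance = 0.15)
  # doubling k halves the median squared error
  msq <- cd$table$median_sq_err
  expect_equal(msq[-length(msq)] / msq[-1], rep(2, 3), tolerance = 0.5)

  expect_error(contraction_diagnostics(structure(list(iid = FALSE),
                                                 class = "iid_family"),
                                       x0 = 0.5, seed = 1),
               "iid")
  expect_error(contraction_diagnostics(x0 = 0.5), "seed")
})

test_that("distance-based knowledge compares distances to the oracle belief", {
  sp <- three_world_space()
  P0 <- uniform_prior(sp)
  A0 <- region_a0(sp)
  # KL variant reduces to P(x0) > P0(x0)
  set.seed(31)
  for (i in 1:10) {
    P <- random_pmf(sp)
    v <- distance_knowledge(P, P0, A0, "kl")
    expect_identical(v$outcome,
                     assess_learning(P, P0, A0)$outcome &&
                       P$mass[2] > P0$mass[2] + 1e-9)
  }
  vdelta <- distance_knowledge(point_mass(sp), P0, A0, "kl")
  expect_equal(vdelta$evidence$distance_P, 0)
  expect_true(vdelta$outcome)

  # 1-D Wasserstein distance to a point mass = mean absolute deviation,
  # cross-checked by quadrature
  bx <- world_space(bounds = c(0, 1), resolution = 400, x0 = 0.3)
  set.seed(33)
  P <- belief_measure(bx, mass = stats::rexp(400))
  xs <- seq(0.5 / 40000, 1 - 0.5 / 40000, length.out = 40000)
  dens <- density_values(P)[pmin(floor(xs * 400) + 1L, 400L)]
  quad <- mean(abs(xs - 0.3) * dens)
  v <- distance_knowledge(P, uniform_prior(bx),
                          region_box(bx, 0.2, 0.4), "wasserstein_1d")
  expect_equal(v$evidence$distance_P, quad, tolerance = 1e-3)
})
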