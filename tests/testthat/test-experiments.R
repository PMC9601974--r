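test_that("student experiment reproduces the two-step posterior moves", {
  tr <- student_experiment(7L)
  o <- student_posterior_oracle(7L)
  expect_equal(tr$P_A, o[2] + o[3], tolerance = 1e-12)
  expect_gt(tr$P_A, 2 / 3)
  expect_gt(tr$posteriors[[1]]$mass[2], 1 / 3)

  tr2 <- student_experiment(7L, z2 = 0L)
  # helper signal z2 = 0 zeroes x3 and renormalises
  expect_equal(tr2$posteriors[[2]]$mass,
               c(o[1], o[2], 0) / (o[1] + o[2]), tolerance = 1e-12)
  expect_lt(tr2$P_A[2], tr2$P_A[1])
  expect_gt(tr2$posteriors[[2]]$mass[2], tr2$posteriors[[1]]$mass[2])

  # the score alone can never pin down x2
  maxp <- max(vapply(0:10, function(d)
    student_experiment(d)$posteriors[[1]]$mass[2], 1))
  expect_lte(maxp, 0.5)

  expect_error(student_experiment(11L), "attainable")
  expect_error(student_experiment(7L, z2 = 2L), "impossible data")
})

test_that("coin experiment tracks exact Beta beliefs and is reproducible", {
  tr0 <- coin_experiment(k_max = 0, seed = 1)
  expect_equal(tr0$I_plus, 0)
  expect_equal(tr0$P_A, 0.2)

  tr <- coin_experiment(k_max = 100, seed = 8)
  m <- tr$heads[100]
  expect_equal(tr$P_A[100],
               stats::pbeta(0.6, 1 + m, 101 - m) -
                 stats::pbeta(0.4, 1 + m, 101 - m), tolerance = 1e-12)

  # same seed and config: identical trajectory
  tr_b <- coin_experiment(k_max = 100, seed = 8)
  expect_identical(tr$P_A, tr_b$P_A)
  expect_identical(tr$heads, tr_b$heads)

  # frozen oracle: 50 heads in 100 tosses, margin 0.1
  sp <- world_space(bounds = c(0, 1), resolution = 1000, x0 = 0.5)
  cm <- coin_model(100)
  post <- posterior_update(uniform_prior(cm$space), cm$model, 50)
  expect_equal(region_prob(post, region_box(cm$space, 0.4, 0.6)),
               0.9582066, tolerance = 1e-2)

  # expected posterior density integrates to 1
  cm20 <- coin_model(20, resolution = 400)
  pbar <- expected_posterior(uniform_prior(cm20$space), cm20$model,
                             "enumerate")
  expect_equal(sum(pbar$mass), 1, tolerance = 1e-9)
})

test_that("dating experiment separates strong learning from knowledge", {
  tr <- dating_experiment()   # optimal dating, reliable book
  expect_true(tr$eq_check$aligned)
  expect_equal(tr$eq_check$I1_plus, log(1 / 0.3), tolerance = 1e-9)
  expect_equal(tr$I_plus, rep(log(1 / 0.3), 2), tolerance = 1e-9)
  v <- assess_strong(tr)
  expect_true(v$evidence$strong_learning)
  expect_true(v$outcome)

  # systematically biased dating: true-world-excluding step 1
  trb <- dating_experiment(step1 = "biased")
  vb <- assess_strong(trb)
  expect_true(vb$evidence$strong_learning)
  expect_false(vb$outcome)       # p1 puts no mass near x0
  expect_equal(region_prob(trb$measures[[1]],
                           ball(trb$space, radius = 0.03)), 0)

  tru <- dating_experiment(step1 = "uniform")
  expect_equal(tru$I_plus[1], 0, tolerance = 1e-9)

  trx <- dating_experiment(famine = c(0.25, 0.61))
  expect_false(trx$eq_check$aligned)

  expect_error(dating_experiment(delta = 0.3), "1/N")
})

test_that("camp experiment handles optimal, biased and ignorant beliefs", {
  tr <- camp_experiment()   # optimal forecast, truthful prophet
  expect_equal(tr$P_A, c(1, 1), tolerance = 1e-12)
  v <- assess_strong(tr)
  expect_true(v$evidence$strong_learning)
  expect_true(is_point_mass_at_x0(tr$measures[[2]]))
  expect_equal(tr$prediction_prob[2], 1)

  # biased but on the correct side: learning without knowledge
  w <- matrix(0, 10, 5); w[3, 2] <- 1
  trb <- camp_experiment(forecast = w, prophet = "ellipse",
                         ellipse_center = c(0.3, 0.3))
  vb <- assess_strong(trb)
  expect_true(vb$evidence$strong_learning)
  expect_false(vb$outcome)
  expect_false(assess_weak(trb)$outcome)

  # ignorant at both steps: no learning
  P0 <- uniform_prior(tr$space)
  wu <- matrix(1 / 50, 10, 5)
  tru <- camp_experiment(forecast = wu, prophet = P0)
  expect_equal(tru$I_plus, c(0, 0), tolerance = 1e-9)
  expect_false(assess_strong(tru)$outcome)

  expect_error(camp_experiment(delta = c(0.2, 0.1)), "delta")
})

test_that("replication probability follows the cell-overlap formula", {
  r <- replication_experiment(delta = 0.1, eps = 0.04,
                              x01 = 0.55, x02 = 0.55)
  expect_equal(r$j0, 6L)
  expect_equal(r$P_A, 0.8, tolerance = 1e-12)

  rf <- replication_experiment(eps = 0.04, x01 = 0.55, x02 = 0.55,
                               info = "full")
  expect_equal(rf$P_A, 1)
  rf2 <- replication_experiment(eps = 0.04, x01 = 0.5, x02 = 0.6,
                                info = "full")
  expect_equal(rf2$P_A, 0)
  expect_identical(rf2$I_plus, -Inf)

  # coarse discernment caps the replication probability when 2 eps < delta
  for (delta in c(0.1, 0.05)) for (eps in c(0.04, 0.02, 0.01)) {
    if (2 * eps >= delta) next
    for (x in seq(0.05, 0.95, by = 0.15)) {
      rr <- replication_experiment(delta = delta, eps = eps,
                                   x01 = x, x02 = x)
      expect_lt(rr$P_A, 1)
    }
  }

  # P(A) is maximal when the tolerance interval covers the true cell most
  grid <- seq(0.501, 0.699, by = 0.002)
  pa <- vapply(grid, function(x2)
    replication_experiment(delta = 0.1, eps = 0.04, x01 = 0.55,
                           x02 = x2)$P_A, 1)
  best <- grid[which.max(pa)]
  expect_true(best > 0.5 && best <= 0.6)  # the cell overlapping most

  # general informed measure: against an independent quadrature oracle
  sp2 <- world_space(bounds = rbind(c(0, 1), c(0, 1)), resolution = 100,
                     x0 = c(0.55, 0.55))
  P2 <- belief_measure(sp2, mass = region_box(sp2, c(0.3, 0.3),
                                              c(0.7, 0.7))$frac)
  rg <- replication_experiment(delta = 0.1, eps = 0.04, P2 = P2)
  # P2 uniform on [0.3,0.7]^2: X1, X2 independent; p1j = 1/4 on cells 4..7
  xs <- seq(0.3 + 1e-4, 0.7 - 1e-4, length.out = 4000)
  ov <- function(x1, j) max(0, min(j * 0.1, x1 + 0.04) -
                              max((j - 1) * 0.1, x1 - 0.04))
  oracle <- mean(vapply(xs, function(x1)
    sum(vapply(4:7, function(j) 0.25 * 10 * ov(x1, j), 1)), 1))
  expect_equal(rg$P_A, oracle, tolerance = 1e-3)
})

test_that("confounding experiment enumerates predictions exactly", {
  cm <- causal_model(beta = c(-1, 1, 1), x0 = c(1, 1, 1))
  ce <- confounding_experiment(cm)
  expect_equal(ce$P0_A, 0.5, tolerance = 1e-12)
  g1_1 <- mean(stats::plogis(c(0, 1)))    # sigma(0), sigma(1) averaged
  expect_equal(ce$table$g_k[2], g1_1, tolerance = 1e-12)
  expect_equal(ce$I1_exposed, log(g1_1 / 0.5), tolerance = 1e-12)
  # full revelation reaches the actual outcome
  expect_equal(ce$table$P_A[4], 1)
  ce0 <- confounding_experiment(causal_model(beta = c(-1, 1, 1),
                                             x0 = c(0, 0, 0)))
  expect_equal(ce0$table$P_A[4], 0)
  # independent covariates: observed and counterfactual curves agree
  expect_equal(ce$table$g_k, ce$table$h_k)

  expect_error(causal_model(beta = rep(0, 25), x0 = rep(1, 25)),
               "n <= 20")

  # weak-learning bookkeeping agrees with the verdict machinery for
  # every true vector at n = 4
  beta4 <- c(-0.5, 1, -1, 0.5)
  for (bits in 0:15) {
    x0 <- as.integer(intToBits(bits))[1:4]
    ce4 <- confounding_experiment(causal_model(beta4, x0))
    tr <- ce4$trajectory
    for (k in seq_along(tr$k)) {
      expect_identical(assess_weak(tr, n = k)$evidence$weak_learning,
                       ce4$table$weak_learning[k + 1L])
    }
  }
})

test_that("experiment generators are reproducible under a fixed seed", {
  a <- coin_experiment(k_max = 50, seed = 99)
  b <- coin_experiment(k_max = 50, seed = 99)
  expect_identical(a$heads, b$heads)
  expect_identical(a$P_A, b$P_A)
  c1 <- contraction_diagnostics(x0 = 0.5, k_grid = c(100, 200),
                                replicates = 200, seed = 4)
  c2 <- contraction_diagnostics(x0 = 0.5, k_grid = c(100, 200),
                                replicates = 200, seed = 4)
  expect_identical(c1$table, c2$table)
})
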