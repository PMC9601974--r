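# Shared fixtures: the three-world student space and random-measure
# generators used by the property-style tests.

three_world_space <- function(x0 = "x2") {
  world_space(points = c("x1", "x2", "x3"), x0 = x0)
}

# Random probability mass function on a finite space.
random_pmf <- function(space) {
  belief_measure(space, mass = stats::rexp(length(space$points)))
}

# Random finite space of n labelled worlds with a random true world.
random_finite_space <- function(n) {
  labels <- paste0("w", seq_len(n))
  world_space(points = labels, x0 = sample(labels, 1L))
}

# Random partition of a finite space into at most m cells (canonical
# cell ids).
random_partition <- function(space, m = 3L) {
  n <- length(space$points)
  repeat {
    a <- sample.int(m, n, replace = TRUE)
    if (length(unique(a)) >= 1L) break
  }
  discernment(space, assignment = a)
}

# Direct binomial arithmetic for the student posterior at score d --
# independent of the package's update path.
student_posterior_oracle <- function(d, pi = c(0.5, 0.8, 0.8), k = 10) {
  lik <- choose(k, d) * pi^d * (1 - pi)^(k - d)
  lik / sum(lik)
}
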