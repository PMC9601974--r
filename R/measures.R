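#' Epistemic belief measure
#'
#' A probability measure on a world space encoding an agent's degrees of
#' belief about which world is true.  On finite spaces it is a probability
#' mass per point; on box spaces a piecewise-constant density represented
#' by per-cell masses, optionally together with a list of atoms (point
#' masses).  Atoms are explicit, never approximated by narrow densities, so
#' that active-information values of `-Inf` are exact.
#'
#' @param space A [world_space()].
#' @param mass Numeric vector of per-point/per-cell masses (non-negative).
#' @param atoms Optional list with fields `x` (a list of atom locations:
#'   labels or numeric vectors) and `w` (numeric weights).
#' @param normalize If `TRUE` (default) rescale so that total mass is 1;
#'   otherwise the total must already be 1 within `1e-9`.
#' @param construction Optional tag recording how the measure was built
#'   (e.g. `"support_excluding"`), used by degenerate-belief scenarios.
#' @return An object of class `belief_measure`.
#' @export
belief_measure <- function(space, mass = NULL, atoms = NULL,
                           normalize = TRUE, construction = NULL) {
  stopifnot(is_world_space(space))
  n <- n_cells(space)
  if (is.null(mass)) mass <- rep(0, n)
  if (length(mass) != n)
    stop("mass must have one entry per point/grid cell", call. = FALSE)
  if (any(mass < -1e-12)) stop("negative mass", call. = FALSE)
  mass <- pmax(as.numeric(mass), 0)
  if (!is.null(atoms)) {
    stopifnot(is.list(atoms$x), is.numeric(atoms$w),
              length(atoms$x) == length(atoms$w))
    if (any(atoms$w < -1e-12)) stop("negative atom weight", call. = FALSE)
    atoms$w <- pmax(atoms$w, 0)
    for (a in atoms$x) {
      ok <- if (space$kind == "finite") a %in% space$points
            else all(a >= space$bounds[, 1L]) && all(a <= space$bounds[, 2L])
      if (!ok) stop("atom outside the space", call. = FALSE)
    }
    if (length(atoms$x) == 0L) atoms <- NULL
  }
  tot <- sum(mass) + sum(atoms$w %||% 0)
  if (normalize) {
    if (tot <= 0) stop("cannot normalize a zero measure", call. = FALSE)
    mass <- mass / tot
    if (!is.null(atoms)) atoms$w <- atoms$w / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop("measure does not total 1", call. = FALSE)
  }
  structure(list(space = space, mass = mass, atoms = atoms,
                 construction = construction),
            class = "belief_measure")
}

#' @export
print.belief_measure <- function(x, ...) {
  cat("Belief measure on a", x$space$kind, "space")
  if (!is.null(x$construction)) cat(" [", x$construction, "]", sep = "")
  cat("\n")
  if (x$space$kind == "finite") {
    m <- x$mass
    names(m) <- x$space$points
    print(utils::head(round(m, 4L), 10L))
  } else {
    cat(sprintf("  %d grid cells, density range [%g, %g]\n",
                n_cells(x$space), min(density_values(x)),
                max(density_values(x))))
  }
  if (!is.null(x$atoms))
    cat("  atoms:", length(x$atoms$x), "with total weight",
        format(sum(x$atoms$w)), "\n")
  invisible(x)
}

#' Per-cell density of a box-space measure
#' @param measure A [belief_measure()] on a box space.
#' @return Numeric vector of densities (cell mass / cell volume).
#' @export
density_values <- function(measure) {
  stopifnot(measure$space$kind == "box")
  measure$mass / cell_volume(measure$space)
}

#' Maximum-entropy ignorance prior
#'
#' The uniform probability measure on the space: equal mass per world
#' (finite) or constant density (box).  It encodes maximal ignorance about
#' which world is true and is the baseline against which learning is
#' measured.
#'
#' @param space A [world_space()].
#' @return A [belief_measure()].
#' @export
uniform_prior <- function(space) {
  belief_measure(space, mass = rep(1, n_cells(space)))
}

#' Point mass at a world
#'
#' The fully informed belief: all probability on a single world.  Equals
#' the optimal measure under maximal discernment.
#'
#' @param space A [world_space()].
#' @param x World (label or numeric vector); defaults to the true world.
#' @return A [belief_measure()].
#' @export
point_mass <- function(space, x = space$x0) {
  if (space$kind == "finite") {
    belief_measure(space, mass = as.numeric(space$points == x))
  } else {
    belief_measure(space, mass = rep(0, n_cells(space)),
                   atoms = list(x = list(as.numeric(x)), w = 1))
  }
}

#' Probability of a truth region
#'
#' `P(A)`: cell masses weighted by coverage fractions, plus the weight of
#' any atoms lying in the region (exact membership).
#'
#' @param measure A [belief_measure()].
#' @param region A [truth_region()] on the same space.
#' @return A probability in `[0, 1]`.
#' @export
region_prob <- function(measure, region) {
  stopifnot(inherits(measure, "belief_measure"),
            inherits(region, "truth_region"))
  if (!same_space(measure$space, region$space))
    stop("measure and region live on different spaces", call. = FALSE)
  p <- sum(measure$mass * region$frac)
  if (!is.null(measure$atoms))
    p <- p + sum(measure$atoms$w *
                   vapply(measure$atoms$x, region$contains, 1))
  min(max(p, 0), 1)
}

#' Likelihood model
#'
#' The statistical model `x -> L(D | x)` linking worlds to data.  The
#' likelihood function is vectorised over worlds; for finite data spaces
#' the outcomes can be enumerated, enabling exact expected posteriors,
#' error rates and mutual information.  When a measurability partition is
#' declared, the likelihood is averaged over each of its cells under the
#' prior before any update, which guarantees that every posterior respects
#' that discernment by construction.
#'
#' @param lik Function `(data, worlds)` returning non-negative likelihood
#'   values; `worlds` is a character vector of labels (finite spaces) or a
#'   matrix of points, one row per world (box spaces).
#' @param outcomes Optional vector/list of enumerable data values.
#' @param sampler Optional function `(n, x0)` drawing data values in the
#'   true world (for Monte Carlo modes).
#' @param measurability Optional [discernment()] the likelihood must
#'   respect.
#' @param label Optional description.
#' @return An object of class `likelihood_model`.
#' @export
likelihood_model <- function(lik, outcomes = NULL, sampler = NULL,
                             measurability = NULL, label = NULL) {
  stopifnot(is.function(lik))
  structure(list(lik = lik, outcomes = outcomes, sampler = sampler,
                 measurability = measurability, label = label),
            class = "likelihood_model")
}

# Likelihood values at every point/grid-cell centre of the space.
lik_values <- function(model, space, data) {
  worlds <- if (space$kind == "finite") space$points else cell_centers(space)
  v <- as.numeric(model$lik(data, worlds))
  if (length(v) != n_cells(space))
    stop("likelihood must return one value per world", call. = FALSE)
  if (any(v < 0) || anyNA(v)) stop("invalid likelihood values", call. = FALSE)
  v
}

# Likelihood at a single world point (label or coordinates).
lik_at <- function(model, space, data, x) {
  w <- if (space$kind == "finite") as.character(x)
       else matrix(as.numeric(x), nrow = 1L)
  as.numeric(model$lik(data, w))
}

#' Bayes posterior update
#'
#' Updates a prior belief with observed data through Bayes' rule: the
#' posterior mass is proportional to `L(data | x)` times the prior.  Prior
#' atoms are updated with the likelihood at their exact location.  If the
#' model declares a measurability partition, `L(data | .)` is first
#' replaced by its prior-weighted average on each partition cell, so the
#' posterior cannot discern worlds beyond that partition.
#'
#' @param prior A [belief_measure()].
#' @param model A [likelihood_model()].
#' @param data One observed data value.
#' @return A posterior [belief_measure()].
#' @export
posterior_update <- function(prior, model, data) {
  stopifnot(inherits(prior, "belief_measure"),
            inherits(model, "likelihood_model"))
  space <- prior$space
  lv <- lik_values(model, space, data)
  if (!is.null(model$measurability)) {
    part <- model$measurability
    if (!same_space(part$space, space))
      stop("measurability partition on a different space", call. = FALSE)
    g <- part$assignment
    wsum <- tapply(prior$mass, g, sum)
    lsum <- tapply(prior$mass * lv, g, sum)
    avg <- ifelse(wsum > 0, lsum / wsum,
                  tapply(lv, g, mean))
    lv <- as.numeric(avg[as.character(g)])
  }
  w <- prior$mass * lv
  atoms <- prior$atoms
  if (!is.null(atoms)) {
    la <- vapply(atoms$x, function(a) lik_at(model, space, data, a), 1)
    atoms$w <- atoms$w * la
  }
  z <- sum(w) + sum(atoms$w %||% 0)
  if (z <= 0)
    stop("impossible data: zero likelihood under the prior support",
         call. = FALSE)
  belief_measure(space, mass = w, atoms = atoms, normalize = TRUE)
}

#' Coarsen a measure to a discernment partition
#'
#' Returns the measure with the same partition-cell totals as the input but
#' whose within-cell shape is proportional to a reference measure (the
#' ignorance baseline).  This is the projection enforcing that the agent
#' discerns nothing within partition cells beyond the reference.  Atoms of
#' the input contribute their weight to the containing cell and are
#' dissolved into the reference shape.
#'
#' @param measure A [belief_measure()].
#' @param discernment A [discernment()].
#' @param reference A [belief_measure()] with positive mass on every
#'   partition cell carrying mass of `measure` (typically the prior).
#' @return A [belief_measure()] satisfying [check_discernment()].
#' @export
coarsen <- function(measure, discernment, reference) {
  stopifnot(inherits(measure, "belief_measure"),
            inherits(discernment, "discernment"),
            inherits(reference, "belief_measure"))
  space <- measure$space
  if (!same_space(space, discernment$space) ||
      !same_space(space, reference$space))
    stop("measure, discernment and reference must share a space",
         call. = FALSE)
  if (!is.null(reference$atoms))
    stop("reference measure must be atom-free", call. = FALSE)
  g <- discernment$assignment
  tot <- tapply(measure$mass, g, sum)
  tot <- as.numeric(tot[as.character(seq_len(discernment$n_parts))])
  tot[is.na(tot)] <- 0
  if (!is.null(measure$atoms)) {
    for (i in seq_along(measure$atoms$x)) {
      j <- g[cell_index(space, measure$atoms$x[[i]])]
      tot[j] <- tot[j] + measure$atoms$w[i]
    }
  }
  ref_tot <- as.numeric(tapply(reference$mass, g, sum)[
    as.character(seq_len(discernment$n_parts))])
  ref_tot[is.na(ref_tot)] <- 0
  if (any(tot > 1e-12 & ref_tot <= 0))
    stop("inconsistent coarsening: cell with positive mass but zero ",
         "reference mass", call. = FALSE)
  scale <- ifelse(ref_tot > 0, tot / ref_tot, 0)
  belief_measure(space, mass = reference$mass * scale[g], normalize = FALSE)
}

#' Does a measure respect a discernment?
#'
#' `TRUE` when, in every partition cell with positive mass under both the
#' measure and the reference, the within-cell conditional distribution of
#' the measure equals that of the reference (within tolerance) — i.e. the
#' measure is invariant under [coarsen()].  A measure with atoms the
#' reference lacks cannot respect a non-trivial partition.
#'
#' @inheritParams coarsen
#' @param tol Comparison tolerance.
#' @return Logical.
#' @export
check_discernment <- function(measure, reference, discernment, tol = 1e-9) {
  if (!is.null(measure$atoms) && sum(measure$atoms$w) > tol &&
      is.null(reference$atoms))
    return(FALSE)
  proj <- coarsen(measure, discernment, reference)
  max(abs(proj$mass - measure$mass)) <= tol
}

#' Discernment-optimal belief
#'
#' The best belief attainable under a discernment: all mass on the
#' partition cell containing the true world, shaped like the reference
#' within it.  Under the finest partition of a finite space this is the
#' point mass at the true world; under the trivial partition it is the
#' reference itself.
#'
#' @param space A [world_space()].
#' @param discernment A [discernment()].
#' @param reference A [belief_measure()] (the ignorance baseline).
#' @return A [belief_measure()].
#' @export
g_optimal <- function(space, discernment, reference) {
  stopifnot(is_world_space(space), inherits(discernment, "discernment"),
            inherits(reference, "belief_measure"))
  j0 <- discernment$assignment[cell_index(space, space$x0)]
  inside <- discernment$assignment == j0
  if (sum(reference$mass[inside]) <= 0)
    stop("degenerate cell: the true world's cell has zero reference mass",
         call. = FALSE)
  belief_measure(space, mass = reference$mass * inside)
}

#' Support-excluding belief measures
#'
#' Degenerate beliefs used to exercise "learning without knowledge":
#' `kind = "true_world"` zeroes out the cell containing the true world
#' (support excludes `x0`); `kind = "correct_proposition"` zeroes all
#' worlds whose truth value agrees with the true world's.  The remaining
#' mass is renormalised; the construction is recorded on the result.
#'
#' @param measure A [belief_measure()] to distort.
#' @param region The proposition's [truth_region()] (needed for
#'   `"correct_proposition"`).
#' @param kind Which support to exclude.
#' @return A [belief_measure()] with a `construction` tag.
#' @export
support_excluding <- function(measure, region = NULL,
                              kind = c("true_world", "correct_proposition")) {
  kind <- match.arg(kind)
  space <- measure$space
  mass <- measure$mass
  if (kind == "true_world") {
    mass[cell_index(space, space$x0)] <- 0
  } else {
    stopifnot(inherits(region, "truth_region"))
    x0_in <- region$contains(space$x0) > 0
    keep <- if (x0_in) region$frac <= 0 else region$frac > 0
    mass <- mass * keep
  }
  belief_measure(space, mass = mass, normalize = TRUE,
                 construction = paste0(kind, "_excluding"))
}

#' Expected posterior belief
#'
#' The posterior averaged over data sets drawn under the true world's data
#' distribution `L(. | x0)`.  With `mode = "enumerate"` the average is
#' exact over the model's enumerable outcomes; with `mode = "monte_carlo"`
#' it averages over seeded draws (the seed is mandatory).
#'
#' @param prior A [belief_measure()].
#' @param model A [likelihood_model()].
#' @param mode `"enumerate"` or `"monte_carlo"`.
#' @param reps Number of Monte Carlo replicates.
#' @param seed Integer seed (required for Monte Carlo).
#' @param x0 True world (defaults to the space's).
#' @return A [belief_measure()].
#' @export
expected_posterior <- function(prior, model,
                               mode = c("enumerate", "monte_carlo"),
                               reps = 1e4, seed = NULL,
                               x0 = prior$space$x0) {
  mode <- match.arg(mode)
  space <- prior$space
  if (mode == "enumerate") {
    if (is.null(model$outcomes))
      stop("enumerate mode needs an enumerable data space", call. = FALSE)
    wts <- vapply(model$outcomes, function(d) lik_at(model, space, d, x0), 1)
    if (abs(sum(wts) - 1) > 1e-6)
      stop("outcome probabilities at x0 do not sum to 1", call. = FALSE)
    draws <- model$outcomes
  } else {
    if (is.null(seed))
      stop("monte_carlo mode requires a seed (reproducibility contract)",
           call. = FALSE)
    set.seed(seed)
    if (!is.null(model$outcomes)) {
      p <- vapply(model$outcomes, function(d) lik_at(model, space, d, x0), 1)
      idx <- sample.int(length(model$outcomes), reps, replace = TRUE,
                        prob = p)
      tab <- table(idx)
      draws <- model$outcomes[as.integer(names(tab))]
      wts <- as.numeric(tab) / reps
    } else {
      if (is.null(model$sampler))
        stop("monte_carlo mode needs enumerable outcomes or a sampler",
             call. = FALSE)
      draws <- model$sampler(reps, x0)
      wts <- rep(1 / reps, length(draws))
    }
  }
  mass <- rep(0, n_cells(space))
  atom_acc <- list()
  for (i in seq_along(draws)) {
    d <- if (is.list(draws)) draws[[i]] else draws[i]
    if (wts[i] <= 0) next
    post <- posterior_update(prior, model, d)
    mass <- mass + wts[i] * post$mass
    if (!is.null(post$atoms)) atom_acc[[length(atom_acc) + 1L]] <-
      list(x = post$atoms$x, w = post$atoms$w * wts[i])
  }
  atoms <- NULL
  if (length(atom_acc)) {
    atoms <- list(x = do.call(c, lapply(atom_acc, `[[`, "x")),
                  w = do.call(c, lapply(atom_acc, `[[`, "w")))
  }
  belief_measure(space, mass = mass, atoms = atoms, normalize = TRUE)
}

#' Serialise a belief measure
#'
#' Finite measures export to a JSON string (labels and masses); box
#' measures to a data frame of cell index and density suitable for CSV.
#'
#' @param measure A [belief_measure()].
#' @return JSON string (finite) or `data.frame` (box).
#' @export
export_measure <- function(measure) {
  if (measure$space$kind == "finite") {
    jsonlite::toJSON(list(points = measure$space$points,
                          mass = measure$mass), digits = NA,
                     auto_unbox = FALSE)
  } else {
    data.frame(cell = seq_len(n_cells(measure$space)),
               density = density_values(measure))
  }
}
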