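#' Space of possible worlds
#'
#' A world space is the parameter space `X` of a statistical model together
#' with a designated true world `x0`; every other point is a counterfactual.
#' Two kinds are supported: a finite set of labelled worlds, and an
#' axis-aligned box in `R^q` represented on a uniform grid of cells so that
#' piecewise-constant belief densities are exactly computable.
#'
#' @param points Character vector of world labels (finite spaces).
#' @param bounds For box spaces, either `c(lo, hi)` (one dimension) or a
#'   `q x 2` matrix of per-dimension closed interval endpoints.
#' @param resolution Integer number of grid cells per dimension (box spaces),
#'   recycled across dimensions; each must be at least 2.
#' @param x0 The true world: a label (finite) or numeric vector of length `q`
#'   inside the bounds (box).
#' @param coords Optional numeric matrix of point coordinates for finite
#'   spaces (one row per world, row names = labels); needed for the Hamming
#'   and Euclidean metrics on finite spaces.
#'
#' @return An object of class `world_space` with fields `kind`
#'   (`"finite"` or `"box"`), `points`/`bounds`/`resolution`, `x0` and `q`.
#' @examples
#' world_space(points = c("x1", "x2", "x3"), x0 = "x2")
#' world_space(bounds = c(0, 1), resolution = 1000, x0 = 0.5)
#' @export
world_space <- function(points = NULL, bounds = NULL, resolution = NULL,
                        x0, coords = NULL) {
  if (!is.null(points) && !is.null(bounds))
    stop("give either `points` (finite) or `bounds` (box), not both",
         call. = FALSE)
  if (!is.null(points)) {
    points <- as.character(points)
    if (length(points) < 1L || anyDuplicated(points))
      stop("invalid space: need at least one distinct world label",
           call. = FALSE)
    if (length(x0) != 1L || !(x0 %in% points))
      stop("invalid space: x0 must be one of the listed worlds",
           call. = FALSE)
    if (!is.null(coords)) {
      coords <- as.matrix(coords)
      if (nrow(coords) != length(points))
        stop("coords must have one row per world", call. = FALSE)
      if (is.null(rownames(coords))) rownames(coords) <- points
    }
    out <- list(kind = "finite", points = points, x0 = as.character(x0),
                q = 1L, coords = coords)
  } else if (!is.null(bounds)) {
    if (is.null(dim(bounds))) bounds <- matrix(bounds, nrow = 1L)
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || any(bounds[, 2L] <= bounds[, 1L]))
      stop("invalid space: each bound must be an interval of positive length",
           call. = FALSE)
    q <- nrow(bounds)
    if (is.null(resolution)) resolution <- 200L
    resolution <- as.integer(rep_len(resolution, q))
    if (any(resolution < 2L))
      stop("invalid space: resolution must be >= 2 per dimension",
           call. = FALSE)
    x0 <- as.numeric(x0)
    if (length(x0) != q || any(x0 < bounds[, 1L]) || any(x0 > bounds[, 2L]))
      stop("invalid space: x0 must lie inside the bounds", call. = FALSE)
    out <- list(kind = "box", bounds = bounds, resolution = resolution,
                x0 = x0, q = q)
  } else {
    stop("empty space specification", call. = FALSE)
  }
  structure(out, class = "world_space")
}

#' @export
print.world_space <- function(x, ...) {
  if (x$kind == "finite") {
    cat("Finite world space with", length(x$points), "worlds:",
        paste(utils::head(x$points, 6L), collapse = ", "),
        if (length(x$points) > 6L) "..." else "", "\n")
  } else {
    cat(sprintf("Box world space in R^%d, %s cells\n", x$q,
                paste(x$resolution, collapse = " x ")))
    for (i in seq_len(x$q))
      cat(sprintf("  dim %d: [%g, %g]\n", i, x$bounds[i, 1L], x$bounds[i, 2L]))
  }
  cat("true world x0:", paste(format(x$x0), collapse = ", "), "\n")
  invisible(x)
}

is_world_space <- function(x) inherits(x, "world_space")

n_cells <- function(space) {
  if (space$kind == "finite") length(space$points) else prod(space$resolution)
}

cell_widths <- function(space) {
  (space$bounds[, 2L] - space$bounds[, 1L]) / space$resolution
}

cell_volume <- function(space) prod(cell_widths(space))

# Midpoints of all grid cells, n x q matrix (dimension 1 varies fastest).
cell_centers <- function(space) {
  stopifnot(space$kind == "box")
  w <- cell_widths(space)
  axes <- lapply(seq_len(space$q), function(i)
    space$bounds[i, 1L] + (seq_len(space$resolution[i]) - 0.5) * w[i])
  as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
}

# Per-dimension cell index of a point under the half-open ((i-1)d, id]
# convention, i = floor(x/d) + 1 clamped to the grid.
axis_index <- function(space, x, dim) {
  w <- cell_widths(space)[dim]
  i <- floor((x - space$bounds[dim, 1L]) / w) + 1L
  pmin(pmax(as.integer(i), 1L), space$resolution[dim])
}

# Linear grid-cell index of a point (box) or point index (finite).
cell_index <- function(space, x) {
  if (space$kind == "finite") return(match(x, space$points))
  idx <- vapply(seq_len(space$q), function(d) axis_index(space, x[d], d), 1L)
  mult <- cumprod(c(1L, space$resolution[-space$q]))
  as.integer(sum((idx - 1L) * mult) + 1L)
}

same_space <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "finite") return(identical(a$points, b$points))
  isTRUE(all.equal(a$bounds, b$bounds)) &&
    identical(a$resolution, b$resolution)
}

#' Truth region of a proposition
#'
#' The set `A = {x : f(x) = 1}` of worlds in which a proposition holds,
#' induced by a binary truth function `f`.  On finite spaces the region is a
#' subset of the labels; on box spaces it is stored as per-cell coverage
#' fractions in `[0, 1]` (1 for cells fully inside, fractional for cells an
#' interval-aligned boundary cuts), together with an exact membership
#' function used for point masses.
#'
#' @param space A [world_space()].
#' @param points Character vector of member labels (finite spaces).
#' @param predicate Function mapping a world (label, or numeric vector for
#'   box spaces) to `TRUE`/`FALSE`; evaluated on labels (finite) or cell
#'   centres (box).
#' @param frac Optional numeric vector of per-cell coverage fractions
#'   (advanced use, box spaces).
#' @param contains Optional exact membership function for points (defaults
#'   to `predicate`, or to `frac > 0` at the containing cell).
#' @param label Optional description.
#' @return An object of class `truth_region`.
#' @examples
#' sp <- world_space(points = c("x1", "x2", "x3"), x0 = "x2")
#' truth_region(sp, points = c("x2", "x3"))
#' @export
truth_region <- function(space, points = NULL, predicate = NULL, frac = NULL,
                         contains = NULL, label = NULL) {
  stopifnot(is_world_space(space))
  if (space$kind == "finite") {
    if (is.null(points)) {
      if (is.null(predicate))
        stop("give `points` or `predicate` for a finite region", call. = FALSE)
      points <- space$points[vapply(space$points, predicate, TRUE)]
    }
    if (!all(points %in% space$points))
      stop("region points must belong to the space", call. = FALSE)
    frac <- as.numeric(space$points %in% points)
    contains <- function(x) as.numeric(x %in% points)
  } else {
    if (is.null(frac)) {
      if (is.null(predicate))
        stop("give `predicate` or `frac` for a box region", call. = FALSE)
      ctr <- cell_centers(space)
      frac <- as.numeric(apply(ctr, 1L, function(r) isTRUE(predicate(r))))
    }
    if (length(frac) != n_cells(space) || any(frac < -1e-12 | frac > 1 + 1e-12))
      stop("region fractions must be one per cell, within [0, 1]",
           call. = FALSE)
    frac <- pmin(pmax(frac, 0), 1)
    if (is.null(contains)) {
      if (!is.null(predicate)) {
        pred <- predicate
        contains <- function(x) as.numeric(isTRUE(pred(x)))
      } else {
        fr <- frac
        contains <- function(x) as.numeric(fr[cell_index(space, x)] > 0)
      }
    }
  }
  structure(list(space = space, frac = frac, contains = contains,
                 label = label),
            class = "truth_region")
}

#' Axis-aligned box region
#'
#' Exact region for a product of closed intervals `[lo_i, hi_i]`, with
#' per-cell coverage computed as the product of one-dimensional overlap
#' fractions, so probabilities of piecewise-constant measures are exact.
#'
#' @param space A box [world_space()].
#' @param lo,hi Numeric vectors of interval endpoints, length `q`.
#' @inheritParams truth_region
#' @return A `truth_region`.
#' @export
region_box <- function(space, lo, hi, label = NULL) {
  stopifnot(is_world_space(space), space$kind == "box")
  lo <- rep_len(as.numeric(lo), space$q)
  hi <- rep_len(as.numeric(hi), space$q)
  if (any(hi < lo)) stop("need lo <= hi in every dimension", call. = FALSE)
  w <- cell_widths(space)
  per_dim <- lapply(seq_len(space$q), function(d) {
    edges_lo <- space$bounds[d, 1L] + (seq_len(space$resolution[d]) - 1L) * w[d]
    edges_hi <- edges_lo + w[d]
    pmin(pmax((pmin(edges_hi, hi[d]) - pmax(edges_lo, lo[d])) / w[d], 0), 1)
  })
  frac <- Reduce(function(a, b) as.vector(outer(a, b)), per_dim)
  contains <- function(x) as.numeric(all(x >= lo & x <= hi))
  truth_region(space, frac = frac, contains = contains, label = label)
}

#' Complement of a truth region
#' @param region A [truth_region()].
#' @return A `truth_region` for `X \ A`.
#' @export
region_complement <- function(region) {
  inner <- region$contains
  structure(list(space = region$space, frac = 1 - region$frac,
                 contains = function(x) 1 - inner(x),
                 label = if (!is.null(region$label))
                   paste0("complement of ", region$label)),
            class = "truth_region")
}

#' Simplest truth set for a proposition about the true world
#'
#' For the truth function that is unique to the true world: `A0 = {x0}` when
#' the proposition holds at `x0`, and `X \ {x0}` otherwise (finite spaces).
#'
#' @param space A finite [world_space()].
#' @param holds_at_x0 Logical; is the proposition true in the true world?
#' @return A `truth_region`.
#' @export
region_a0 <- function(space, holds_at_x0 = TRUE) {
  stopifnot(is_world_space(space), space$kind == "finite")
  r <- truth_region(space, points = space$x0)
  if (holds_at_x0) r else region_complement(r)
}

#' @export
print.truth_region <- function(x, ...) {
  meas <- if (x$space$kind == "finite") sum(x$frac)
          else sum(x$frac) * cell_volume(x$space)
  cat("Truth region", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "on a", x$space$kind, "space; base measure", format(meas), "\n")
  invisible(x)
}

#' Metrics on world spaces
#'
#' Distance functions used for the closed balls of the knowledge
#' definitions: Euclidean on box spaces (or finite spaces with coordinates),
#' Hamming on finite spaces of binary vectors, and the categorical 0/1
#' metric on any finite space.
#'
#' @param kind One of `"euclidean"`, `"hamming"`, `"categorical"`.
#' @return An object of class `world_metric`.
#' @export
world_metric <- function(kind = c("euclidean", "hamming", "categorical")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "world_metric")
}

#' Default metric for a space
#'
#' Euclidean for box spaces; Hamming for finite spaces with binary-vector
#' coordinates; categorical otherwise.
#' @param space A [world_space()].
#' @return A [world_metric()].
#' @export
default_metric <- function(space) {
  if (space$kind == "box") return(world_metric("euclidean"))
  if (!is.null(space$coords) && all(space$coords %in% c(0, 1)))
    return(world_metric("hamming"))
  world_metric("categorical")
}

metric_distance <- function(metric, space, x, y) {
  switch(metric$kind,
    categorical = as.numeric(!identical(x, y)),
    hamming = {
      cx <- space$coords[x, ]; cy <- space$coords[y, ]
      sum(abs(cx - cy))
    },
    euclidean = {
      if (space$kind == "finite") {
        cx <- space$coords[x, ]; cy <- space$coords[y, ]
      } else {
        cx <- x; cy <- y
      }
      sqrt(sum((cx - cy)^2))
    })
}

#' Closed ball around the true world
#'
#' `B_eps(x0) = {x : d(x, x0) <= eps}`, the region whose probabilities under
#' the agent's and the ignorant measure decide whether learning is
#' justified.  One-dimensional Euclidean balls are exact intervals; in two
#' or more dimensions cell membership is evaluated at cell centres while the
#' membership function for point masses stays exact.
#'
#' @param space A [world_space()].
#' @param metric A [world_metric()] applicable to the space kind.
#' @param radius Non-negative radius `eps`.
#' @param center Optional ball centre (defaults to the true world `x0`).
#' @return A [truth_region()].
#' @export
ball <- function(space, metric = default_metric(space), radius,
                 center = space$x0) {
  stopifnot(is_world_space(space), inherits(metric, "world_metric"))
  if (radius < 0) stop("ball radius must be non-negative", call. = FALSE)
  if (metric$kind %in% c("hamming", "categorical") && space$kind != "finite")
    stop(metric$kind, " metric applies to finite spaces only", call. = FALSE)
  if (space$kind == "finite") {
    inside <- vapply(space$points, function(p)
      metric_distance(metric, space, p, center) <= radius, TRUE)
    return(truth_region(space, points = space$points[inside],
                        label = sprintf("ball(eps=%g)", radius)))
  }
  if (space$q == 1L) {
    return(region_box(space, center - radius, center + radius,
                      label = sprintf("ball(eps=%g)", radius)))
  }
  ctr <- cell_centers(space)
  d2 <- rowSums((ctr - matrix(center, nrow(ctr), space$q, byrow = TRUE))^2)
  truth_region(space, frac = as.numeric(d2 <= radius^2),
               contains = function(x) as.numeric(sum((x - center)^2) <= radius^2),
               label = sprintf("ball(eps=%g)", radius))
}

#' Radius grid for "for all eps > 0" checks
#'
#' The knowledge definitions quantify ball inequalities over every positive
#' radius; since ball probabilities are monotone in the radius and all
#' measures are piecewise constant, a finite grid is adequate.  Finite
#' categorical spaces need only `{0, 1}`; Hamming spaces use the integer
#' radii; box spaces use a geometric grid of 32 radii from the cell width up
#' to the space diameter.
#'
#' @param space A [world_space()].
#' @param metric A [world_metric()].
#' @param n Number of radii for box spaces.
#' @return Numeric vector of radii.
#' @export
epsilon_grid <- function(space, metric = default_metric(space), n = 32L) {
  if (space$kind == "finite") {
    if (metric$kind == "hamming") return(0:ncol(space$coords))
    return(c(0, 1))
  }
  w <- min(cell_widths(space))
  diam <- sqrt(sum((space$bounds[, 2L] - space$bounds[, 1L])^2))
  exp(seq(log(w), log(diam), length.out = n))
}

#' Discernment partition
#'
#' A finite partition of the world space representing the sigma-algebra
#' that limits which distinctions between worlds the agent can make: within
#' each cell the agent's beliefs must keep the shape of the ignorance
#' baseline.  Stored as an assignment of every point/grid cell to a
#' partition cell, which enforces disjointness and coverage by
#' construction.
#'
#' @param space A [world_space()].
#' @param cells A list of partition cells: character vectors of labels
#'   (finite spaces) or `truth_region`s with 0/1 cell coverage (box spaces,
#'   boundaries must align with the grid).
#' @param assignment Alternative to `cells`: an integer vector assigning
#'   each point/grid cell to a partition cell.
#' @param label Optional description of the generating variable.
#' @return An object of class `discernment`.
#' @examples
#' sp <- world_space(points = c("x1", "x2", "x3"), x0 = "x2")
#' discernment(sp, cells = list("x1", c("x2", "x3")))
#' @export
discernment <- function(space, cells = NULL, assignment = NULL, label = NULL) {
  stopifnot(is_world_space(space))
  n <- n_cells(space)
  if (is.null(assignment)) {
    if (is.null(cells)) stop("give `cells` or `assignment`", call. = FALSE)
    assignment <- rep(NA_integer_, n)
    for (j in seq_along(cells)) {
      cl <- cells[[j]]
      idx <- if (inherits(cl, "truth_region")) {
        if (any(cl$frac > 1e-12 & cl$frac < 1 - 1e-12))
          stop("invalid partition: cell boundaries must align with the grid",
               call. = FALSE)
        which(cl$frac > 0.5)
      } else if (space$kind == "finite") {
        match(as.character(cl), space$points)
      } else {
        as.integer(cl)
      }
      if (anyNA(idx)) stop("invalid partition cell", call. = FALSE)
      if (any(!is.na(assignment[idx])))
        stop("invalid partition: overlapping cells", call. = FALSE)
      assignment[idx] <- j
    }
    if (anyNA(assignment))
      stop("invalid partition: cells do not cover the space", call. = FALSE)
    assignment <- match(assignment, unique(assignment))
  } else {
    assignment <- as.integer(assignment)
    if (length(assignment) != n || anyNA(assignment))
      stop("assignment must map every point/grid cell to a partition cell",
           call. = FALSE)
    # canonical form: cells numbered by first occurrence
    assignment <- match(assignment, unique(assignment))
  }
  structure(list(space = space, assignment = assignment,
                 n_parts = max(assignment), label = label),
            class = "discernment")
}

#' @rdname discernment
#' @export
discernment_trivial <- function(space)
  discernment(space, assignment = rep(1L, n_cells(space)), label = "trivial")

#' @rdname discernment
#' @export
discernment_finest <- function(space)
  discernment(space, assignment = seq_len(n_cells(space)), label = "finest")

#' Quantisation discernment on a box space
#'
#' Partition of a box space into half-open cells `((i-1)delta, i delta]`
#' per dimension, the sigma-algebra generated by measuring each coordinate
#' with precision `delta`.  Product partitions (different precisions per
#' dimension, or full discernment in some dimensions with `delta = 0`) are
#' supported.  The grid resolution must be an integer multiple of
#' `1/delta` in each quantised dimension so cell boundaries align exactly.
#'
#' @param space A box [world_space()].
#' @param delta Numeric vector of precisions per dimension (recycled);
#'   `0` means full discernment in that dimension.
#' @param label Optional description.
#' @return A [discernment()].
#' @export
discernment_quantize <- function(space, delta, label = NULL) {
  stopifnot(is_world_space(space), space$kind == "box")
  delta <- rep_len(as.numeric(delta), space$q)
  w <- cell_widths(space)
  per_dim <- lapply(seq_len(space$q), function(d) {
    if (delta[d] <= 0) return(seq_len(space$resolution[d]))
    step <- delta[d] / w[d]
    if (abs(step - round(step)) > 1e-9)
      stop("resolution must be an integer multiple of 1/delta", call. = FALSE)
    rep(seq_len(space$resolution[d] / round(step)), each = round(step))
  })
  grid <- expand.grid(per_dim, KEEP.OUT.ATTRS = FALSE)
  sizes <- vapply(per_dim, max, 1L)
  mult <- cumprod(c(1L, sizes[-space$q]))
  assignment <- as.integer(as.matrix(grid) %*% mult - sum(mult) + 1L)
  discernment(space, assignment = assignment,
              label = label %||% sprintf("quantized(delta=%s)",
                                         paste(delta, collapse = ",")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is one discernment a refinement of another?
#'
#' `TRUE` when every cell of `fine` lies inside a single cell of `coarse`,
#' i.e. the fine partition generates at least the distinctions of the
#' coarse one.  This is the nesting relation of an increasing discernment
#' sequence.
#'
#' @param fine,coarse [discernment()]s on the same space.
#' @return Logical.
#' @export
is_refinement <- function(fine, coarse) {
  stopifnot(inherits(fine, "discernment"), inherits(coarse, "discernment"))
  if (!same_space(fine$space, coarse$space))
    stop("discernments live on different spaces", call. = FALSE)
  hits <- tapply(coarse$assignment, fine$assignment,
                 function(v) length(unique(v)))
  all(hits == 1L)
}

#' @export
print.discernment <- function(x, ...) {
  cat("Discernment with", x$n_parts, "cells on a", x$space$kind, "space",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  invisible(x)
}
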