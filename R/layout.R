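# Force-directed spring-embedder layout, written from scratch: each edge
# is a spring obeying Hooke's law, each node a like charge obeying
# Coulomb's law (inverse-square repulsion between every node pair), and
# the drawing is the force equilibrium reached by damped relaxation.

#' Layout parameters
#'
#' The physical model has no canonical constants; these defaults scale the
#' two-node equilibrium to order 1 (with `k_s = L = k_r = 1`, two connected
#' nodes settle at the real root of `d^3 - d^2 - 1 = 0`, about 1.47).
#'
#' @param spring_constant `k_s > 0`, Hooke constant of every edge spring.
#' @param natural_length `L > 0`, rest length of every edge spring.
#' @param repulsion_constant `k_r > 0`, Coulomb constant; repulsion between
#'   nodes at distance `d` has magnitude `k_r / d^2`.
#' @param step_size initial displacement per unit force (> 0); halved
#'   adaptively whenever the maximum force increases.
#' @param max_iterations iteration budget of [relax()].
#' @param force_tolerance convergence threshold on the maximum per-node
#'   force magnitude.
#' @param centering_strength weak restoring force `-c * position` pulling
#'   nodes toward the origin; `NULL` (default) enables a small value
#'   (0.01) only for graphs that are disconnected (where pure repulsion
#'   would otherwise drive components apart without bound), 0 disables it.
#' @param seed seed for the initial placement.
#' @return object of class `layout_params`.
#' @export
layout_params <- function(spring_constant = 1, natural_length = 1,
                          repulsion_constant = 1, step_size = 0.05,
                          max_iterations = 10000L, force_tolerance = 1e-4,
                          centering_strength = NULL, seed = 1L) {
  for (v in c(spring_constant, natural_length, repulsion_constant,
              step_size, force_tolerance)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      .stopf("layout constants must be single positive numbers")
    }
  }
  if (!.is_count(max_iterations)) .stopf("max_iterations must be a positive integer")
  if (!is.null(centering_strength) &&
      (!is.numeric(centering_strength) || centering_strength < 0)) {
    .stopf("centering_strength must be >= 0 (or NULL for automatic)")
  }
  structure(list(spring_constant = spring_constant,
                 natural_length = natural_length,
                 repulsion_constant = repulsion_constant,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 force_tolerance = force_tolerance,
                 centering_strength = centering_strength,
                 seed = as.integer(seed)),
            class = "layout_params")
}

.new_layout <- function(positions, residual = NA_real_,
                        iterations_used = 0L, centering = 0) {
  structure(list(positions = positions, residual = residual,
                 iterations_used = as.integer(iterations_used),
                 centering_strength = centering),
            class = "cooc_layout")
}

#' @export
print.cooc_layout <- function(x, ...) {
  cat(sprintf("<cooc_layout> %d nodes, residual %.3g after %d iterations\n",
              nrow(x$positions), x$residual, x$iterations_used))
  invisible(x)
}

#' Seeded initial placement
#'
#' Positions sampled uniformly in the unit square; exact collisions are
#' re-jittered so no two nodes coincide. Deterministic per
#' `(node order, seed)`.
#'
#' @param nodes character vector of node names (>= 1).
#' @param seed integer seed.
#' @return a `cooc_layout` whose `positions` is an `n x 2` matrix with
#'   `nodes` as row names.
#' @export
initial_placement <- function(nodes, seed = 1L) {
  n <- length(nodes)
  if (n < 1L) .stopf("initial_placement needs >= 1 node")
  pos <- withr::with_seed(as.integer(seed), {
    p <- cbind(stats::runif(n), stats::runif(n))
    for (tries in 1:100) {
      dup <- duplicated(p)
      if (!any(dup)) break
      p[dup, ] <- p[dup, , drop = FALSE] +
        matrix(stats::runif(2 * sum(dup), -1e-3, 1e-3), ncol = 2)
    }
    p
  })
  rownames(pos) <- nodes
  colnames(pos) <- c("x", "y")
  .new_layout(pos)
}

# Is the graph (nodes + edges) connected? Empty edge sets with > 1 node
# count as disconnected.
.is_connected <- function(graph) {
  n <- length(graph$nodes)
  if (n <= 1L) return(TRUE)
  if (nrow(graph$edges) == 0L) return(FALSE)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- idx[[graph$edges$word1[e]]]
    j <- idx[[graph$edges$word2[e]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

.resolve_centering <- function(graph, params) {
  params$centering_strength %||% (if (.is_connected(graph)) 0 else 0.01)
}

#' Compute per-node forces
#'
#' For each edge `(u, v)` at distance `d`, a spring force of magnitude
#' `k_s * (d - L)` acts on both endpoints, attracting when the spring is
#' stretched (`d > L`) and repelling when compressed. Every node pair at
#' distance `d` additionally repels with magnitude `k_r / d^2`. An optional
#' centering force `-c * position` is added. Forces are summed per node;
#' Newton's third law holds for every pairwise term. Distances are
#' regularized below `1e-9` to keep coincident points finite.
#'
#' @param graph a [build_graph()] result.
#' @param layout a `cooc_layout` covering all graph nodes.
#' @param params a [layout_params()].
#' @param centering_strength override of the resolved centering constant
#'   (default: resolve from `params` and graph connectivity).
#' @return `n x 2` matrix of force vectors, rows named by node.
#' @export
compute_forces <- function(graph, layout, params = layout_params(),
                           centering_strength = NULL) {
  stopifnot(inherits(graph, "cooc_graph"), inherits(layout, "cooc_layout"))
  P <- layout$positions[graph$nodes, , drop = FALSE]
  n <- nrow(P)
  cs <- centering_strength %||% .resolve_centering(graph, params)
  dx <- outer(P[, 1L], P[, 1L], "-")   # dx[i, j] = x_i - x_j
  dy <- outer(P[, 2L], P[, 2L], "-")
  d <- sqrt(dx^2 + dy^2)
  d <- pmax(d, 1e-9)
  diag(d) <- Inf                       # no self-repulsion
  inv3 <- 1 / d^3
  Fx <- params$repulsion_constant * rowSums(dx * inv3)
  Fy <- params$repulsion_constant * rowSums(dy * inv3)
  ne <- nrow(graph$edges)
  if (ne > 0L) {
    idx <- stats::setNames(seq_len(n), graph$nodes)
    iu <- idx[graph$edges$word1]
    iv <- idx[graph$edges$word2]
    ex <- P[iu, 1L] - P[iv, 1L]
    ey <- P[iu, 2L] - P[iv, 2L]
    ed <- pmax(sqrt(ex^2 + ey^2), 1e-9)
    mag <- params$spring_constant * (ed - params$natural_length)
    # force on u points toward v when stretched: -(mag) * unit(u - v)
    fux <- -mag * ex / ed
    fuy <- -mag * ey / ed
    grp <- c(iu, iv)
    addx <- rowsum(c(fux, -fux), grp)
    addy <- rowsum(c(fuy, -fuy), grp)
    at <- as.integer(rownames(addx))
    Fx[at] <- Fx[at] + addx[, 1L]
    Fy[at] <- Fy[at] + addy[, 1L]
  }
  if (cs > 0) {
    Fx <- Fx - cs * P[, 1L]
    Fy <- Fy - cs * P[, 2L]
  }
  F <- cbind(x = Fx, y = Fy)
  rownames(F) <- graph$nodes
  F
}

#' Relax a graph to force equilibrium
#'
#' Damped iteration: `position <- position + step * force`, with the step
#' halved whenever the maximum force magnitude grows by more than 5%
#' (and recovering slowly, never beyond `step_size`, while the force
#' descends), so overshoot is damped and the force sequence is eventually
#' non-increasing. Stops when the maximum per-node force drops below
#' `force_tolerance` or the iteration budget is spent. Deterministic for a
#' given `(graph, params, seed)`.
#'
#' @param graph a [build_graph()] result with >= 1 node.
#' @param params a [layout_params()].
#' @return a `cooc_layout` with `residual` (final maximum force magnitude)
#'   and `iterations_used` filled in.
#' @export
relax <- function(graph, params = layout_params()) {
  stopifnot(inherits(graph, "cooc_graph"))
  if (length(graph$nodes) < 1L) .stopf("cannot lay out an empty graph")
  cs <- .resolve_centering(graph, params)
  layout <- initial_placement(graph$nodes, params$seed)
  P <- layout$positions
  step <- params$step_size
  lay <- .new_layout(P, centering = cs)
  F <- compute_forces(graph, lay, params, centering_strength = cs)
  fmax <- max(sqrt(rowSums(F^2)))
  it <- 0L
  while (fmax >= params$force_tolerance && it < params$max_iterations) {
    P <- P + step * F
    if (any(!is.finite(P))) {
      .stopf("layout diverged (non-finite positions at iteration %d; step %.3g)",
             it, step)
    }
    lay$positions <- P
    F <- compute_forces(graph, lay, params, centering_strength = cs)
    fmax_new <- max(sqrt(rowSums(F^2)))
    if (fmax_new > fmax * 1.05) {
      # genuine overshoot (not the benign jitter of a descending path):
      # damp harder
      step <- step / 2
    } else {
      # recover slowly after transients so the step does not freeze at
      # a microscopic value; never beyond the configured step size
      step <- min(step * 1.05, params$step_size)
    }
    fmax <- fmax_new
    it <- it + 1L
  }
  .new_layout(P, residual = fmax, iterations_used = it, centering = cs)
}

#' Push overlapping nodes apart
#'
#' A greedy post-pass standing in for manual de-overlapping: node pairs
#' closer than `min_separation` are pushed apart symmetrically along their
#' connecting direction until all pairwise distances reach the minimum or
#' the pass budget is exhausted. Best effort — neighborhood structure is
#' preserved approximately, nothing is guaranteed about edge crossings.
#'
#' @param layout a `cooc_layout`.
#' @param graph the graph the layout belongs to (node order).
#' @param min_separation minimum allowed pairwise distance (default 0.05).
#' @param max_passes pass budget (default 200).
#' @return the adjusted `cooc_layout`.
#' @export
reduce_overlap <- function(layout, graph, min_separation = 0.05,
                           max_passes = 200L) {
  stopifnot(inherits(layout, "cooc_layout"), inherits(graph, "cooc_graph"))
  P <- layout$positions[graph$nodes, , drop = FALSE]
  n <- nrow(P)
  if (n >= 2L) {
    for (pass in seq_len(max_passes)) {
      moved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          delta <- P[i, ] - P[j, ]
          d <- sqrt(sum(delta^2))
          if (d >= min_separation) next
          if (d < 1e-12) {
            # coincident: deterministic direction from the pair index
            ang <- 2 * pi * (i * n + j) / (n * n + 1)
            unit <- c(cos(ang), sin(ang))
          } else {
            unit <- delta / d
          }
          push <- (min_separation - d) / 2 + 1e-12
          P[i, ] <- P[i, ] + unit * push
          P[j, ] <- P[j, ] - unit * push
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  layout$positions <- P
  layout
}
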