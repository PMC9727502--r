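#' All-pairs free-energy distance matrix
#'
#' Computes the matrix `D` with `D[i, j]` the free energy of travelling
#' from state `i` to goal `j` under the policy that is free-energy-optimal
#' for goal `j`: one [free_energy_solve()] per goal column, each column a
#' full per-state free-energy profile. The diagonal is zero. At large
#' `beta` the matrix approaches the all-pairs shortest-path distances; as
#' `beta` shrinks the entries become increasingly asymmetric and may
#' violate the triangle inequality.
#'
#' @param spec A [grid_spec()].
#' @param beta Strictly positive trade-off parameter.
#' @param goals Optional subset of 0-based goal states (columns to
#'   compute); defaults to all states. Rows always cover all states.
#' @param ... Passed to [free_energy_solve()] (tolerances, `log_base`, ...).
#'
#' @return An object of class `fe_distance`: `D` (rows = start states,
#'   columns = goal states, dimnames are 0-based state indices), `beta`,
#'   `goals`, `symmetrized` flag, and per-goal convergence diagnostics.
#' @export
#' @examples
#' pd <- pairwise_free_energy(grid_spec(3, 3), beta = 1e7)
#' max(abs(diag(pd$D)))  # zero diagonal
pairwise_free_energy <- function(spec, beta, goals = NULL, ...) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- spec$n_states
  if (is.null(goals)) goals <- seq_len(n) - 1L
  goals <- as.integer(goals)
  if (any(goals < 0L | goals >= n)) stop("goal index out of range", call. = FALSE)
  D <- matrix(NA_real_, n, length(goals),
              dimnames = list(seq_len(n) - 1L, goals))
  diag_ok <- vector("list", length(goals))
  for (k in seq_along(goals)) {
    g <- goals[k]
    sol <- tryCatch(
      free_energy_solve(build_gridworld(spec, g), beta, ...),
      error = function(e) stop(sprintf("pairwise_free_energy: solve failed for goal %d: %s",
                                       g, conditionMessage(e)), call. = FALSE)
    )
    D[, k] <- sol$F
    diag_ok[[k]] <- sol$diagnostics
  }
  structure(list(D = D, beta = beta, goals = goals, symmetrized = FALSE,
                 diagnostics = diag_ok),
            class = "fe_distance")
}

#' @export
print.fe_distance <- function(x, ...) {
  cat(sprintf("<fe_distance> %d x %d, beta=%g%s\n", nrow(x$D), ncol(x$D),
              x$beta, if (x$symmetrized) ", symmetrized" else ""))
  invisible(x)
}

#' Symmetrize a distance matrix
#'
#' Averages reciprocal trajectories: `Dsym = (D + t(D)) / 2`. The
#' operation is idempotent. Used to turn the directed free-energy distances
#' into a symmetric dissimilarity suitable for multidimensional scaling.
#'
#' @param D An `fe_distance` object or a square numeric matrix.
#' @return Same type as the input, with the symmetrized matrix and (for
#'   `fe_distance`) the `symmetrized` flag set.
#' @export
symmetrize <- function(D) {
  if (inherits(D, "fe_distance")) {
    D$D <- symmetrize(D$D)
    D$symmetrized <- TRUE
    return(D)
  }
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("`D` must be square", call. = FALSE)
  (D + t(D)) / 2
}

#' Audit quasi-metric axioms of a distance matrix
#'
#' Exhaustively tests the three quasi-metric axioms on a zero-diagonal
#' matrix: non-negativity (`d_ij >= 0`), identity of indiscernibles
#' (`d_ij = 0` iff `i = j`), and the directed triangle inequality
#' `d_ik <= d_ij + d_jk` over all ordered triples. The negative optimal
#' value of a cost-only MDP always passes; free-energy distances at small
#' `beta` violate the triangle inequality, sometimes drastically.
#'
#' Triangle violations are reported with their normalized magnitude
#' `(d_ij + d_jk - d_ik) / d_ik` (negative at a violation: the two-leg
#' route undercuts the direct distance by that fraction).
#'
#' @param D An `fe_distance` object or square zero-diagonal matrix.
#' @param normalized_tol Violations smaller (in relative magnitude) than
#'   this are attributed to solver noise and not counted.
#' @return An object of class `quasimetric_report`: logical axiom results
#'   `d1`, `d2`, `d3`, counts, the worst violating ordered triple
#'   (0-based `(i, j, k)` for `i -> j -> k` vs direct `i -> k`) with its
#'   normalized magnitude, and a table of all violating triples.
#' @export
quasimetric_audit <- function(D, normalized_tol = 1e-6) {
  if (inherits(D, "fe_distance")) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("`D` must be square", call. = FALSE)

  d1_ok <- all(D >= -1e-12)
  offdiag <- D[row(D) != col(D)]
  d2_ok <- all(abs(diag(D)) <= 1e-9) && all(offdiag > 1e-9)

  viol <- NULL
  worst <- NULL
  worst_mag <- 0
  for (j in seq_len(n)) {
    two_leg <- outer(D[, j], D[j, ], "+")       # i -> j -> k
    rel <- (two_leg - D) / D                    # < 0 where the detour wins
    rel[!is.finite(rel)] <- 0
    rel[, j] <- 0; rel[j, ] <- 0                # require distinct i, j, k
    diag(rel) <- 0
    hit <- which(rel < -normalized_tol, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      mags <- rel[hit]
      viol <- rbind(viol, data.frame(i = hit[, 1] - 1L, j = j - 1L,
                                     k = hit[, 2] - 1L,
                                     normalized_diff = mags))
      m <- which.min(mags)
      if (-mags[m] > worst_mag) {
        worst_mag <- -mags[m]
        worst <- c(i = hit[m, 1] - 1L, j = j - 1L, k = hit[m, 2] - 1L)
      }
    }
  }
  n_viol <- if (is.null(viol)) 0L else nrow(viol)
  structure(
    list(d1 = d1_ok, d2 = d2_ok, d3 = n_viol == 0L,
         n_triples = n * (n - 1L) * (n - 2L),
         n_violations = n_viol,
         worst_triple = worst,
         worst_magnitude = worst_mag,
         violations = viol,
         normalized_tol = normalized_tol),
    class = "quasimetric_report"
  )
}

#' @export
print.quasimetric_report <- function(x, ...) {
  cat(sprintf("<quasimetric_report> D1 %s, D2 %s, D3 %s (%d/%d ordered triples violated)\n",
              ifelse(x$d1, "ok", "VIOLATED"), ifelse(x$d2, "ok", "VIOLATED"),
              ifelse(x$d3, "ok", "VIOLATED"), x$n_violations, x$n_triples))
  if (!is.null(x$worst_triple))
    cat(sprintf("  worst: <%d, %d, %d>, normalized magnitude %.4g\n",
                x$worst_triple[1], x$worst_triple[2], x$worst_triple[3],
                x$worst_magnitude))
  invisible(x)
}

#' Metric multidimensional scaling by stress majorization
#'
#' Embeds a symmetric zero-diagonal dissimilarity matrix into 2 or 3
#' Euclidean dimensions by minimizing normalized stress-1,
#' `sqrt(sum((delta_ij - d_ij)^2) / sum(delta_ij^2))`, with the SMACOF
#' majorization update. The first start is the classical (Torgerson)
#' scaling solution; remaining restarts are random. Coordinates are
#' defined only up to rotation, reflection and translation: compare
#' embeddings via stress or after Procrustes alignment, never coordinate
#' by coordinate.
#'
#' @param Dsym An `fe_distance` (symmetrized) or symmetric numeric matrix.
#' @param dim Embedding dimension, 2 or 3.
#' @param seed Integer seed controlling the random restarts.
#' @param restarts Number of starts (first is classical scaling).
#' @param max_iter,tol Majorization iteration cap and relative stress
#'   improvement threshold.
#' @return An object of class `embedding_result`: `coordinates`
#'   (n x dim), `stress` (normalized stress-1), `seed`, `dim`, `restarts`.
#' @export
mds_embed <- function(Dsym, dim = 2, seed = 1L, restarts = 4L,
                      max_iter = 500L, tol = 1e-12) {
  if (inherits(Dsym, "fe_distance")) Dsym <- symmetrize(Dsym)$D
  Dsym <- as.matrix(Dsym)
  n <- nrow(Dsym)
  if (n != ncol(Dsym) || max(abs(Dsym - t(Dsym))) > 1e-8)
    stop("`Dsym` must be a symmetric square matrix", call. = FALSE)
  if (!dim %in% c(2L, 3L)) stop("`dim` must be 2 or 3", call. = FALSE)

  denom <- sum(Dsym^2)
  stress_of <- function(X) {
    dd <- as.matrix(stats::dist(X))
    sqrt(sum((Dsym - dd)^2) / denom)
  }
  smacof <- function(X) {
    s_old <- stress_of(X)
    for (it in seq_len(max_iter)) {
      dd <- as.matrix(stats::dist(X))
      ratio <- ifelse(dd > 1e-12, Dsym / dd, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n                    # Guttman transform
      s_new <- stress_of(X)
      if (s_old - s_new < tol * max(s_old, 1e-300)) break
      s_old <- s_new
    }
    list(X = X, stress = stress_of(X))
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    X0 <- if (r == 1L) {
      cmd <- stats::cmdscale(Dsym, k = dim)
      if (ncol(cmd) < dim) cbind(cmd, matrix(0, n, dim - ncol(cmd))) else cmd
    } else {
      matrix(stats::rnorm(n * dim, sd = stats::sd(Dsym)), n, dim)
    }
    fit <- smacof(X0)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$X
  rownames(coords) <- seq_len(n) - 1L
  colnames(coords) <- c("x", "y", "z")[seq_len(dim)]
  structure(list(coordinates = coords, stress = best$stress,
                 seed = as.integer(seed), dim = as.integer(dim),
                 restarts = as.integer(restarts)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points in %dD, stress-1 = %.4g (seed %d, %d restarts)\n",
              nrow(x$coordinates), x$dim, x$stress, x$seed, x$restarts))
  invisible(x)
}
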