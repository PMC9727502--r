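#' Grid specification for an empty rectangular gridworld
#'
#' Describes the geometry of an empty rectangular gridworld: its width
#' (number of columns), height (number of rows) and the action
#' neighbourhood. The Manhattan neighbourhood allows the four cardinal
#' moves; the Moore neighbourhood adds the four diagonals.
#'
#' States are numbered row-major from the top-left corner: state 0 is the
#' top-left cell, numbering increases along columns first and then row by
#' row, so state `row * width + col`.
#'
#' @param width Number of columns (positive integer).
#' @param height Number of rows (positive integer).
#' @param neighborhood Either `"manhattan"` (4 actions) or `"moore"`
#'   (8 actions).
#'
#' @return An object of class `grid_spec` with fields `width`, `height`,
#'   `neighborhood`, `n_states`, and the ordered action table.
#' @export
#' @examples
#' grid_spec(5, 5, "manhattan")
#' grid_spec(7, 7, "moore")
grid_spec <- function(width, height, neighborhood = c("manhattan", "moore")) {
  neighborhood <- match.arg(neighborhood)
  if (!is.numeric(width) || length(width) != 1L || width < 1 || width != round(width))
    stop("`width` must be a positive integer", call. = FALSE)
  if (!is.numeric(height) || length(height) != 1L || height < 1 || height != round(height))
    stop("`height` must be a positive integer", call. = FALSE)
  structure(
    list(
      width = as.integer(width),
      height = as.integer(height),
      neighborhood = neighborhood,
      n_states = as.integer(width * height),
      actions = action_table(neighborhood)
    ),
    class = "grid_spec"
  )
}

# Fixed action order: cardinals up, left, down, right; Moore appends the
# diagonals up-left, down-left, down-right, up-right. drow is the change in
# row (negative = towards the top of the grid), dcol the change in column.
action_table <- function(neighborhood) {
  tab <- data.frame(
    action = c("up", "left", "down", "right",
               "up-left", "down-left", "down-right", "up-right"),
    drow = c(-1L, 0L, 1L, 0L, -1L, 1L, 1L, -1L),
    dcol = c(0L, -1L, 0L, 1L, -1L, -1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  if (neighborhood == "manhattan") tab[1:4, ] else tab
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d (%s, %d actions), %d states\n",
              x$height, x$width, x$neighborhood, nrow(x$actions), x$n_states))
  invisible(x)
}

#' Convert grid coordinates to a state index and back
#'
#' State numbering is row-major from the top-left corner: state
#' `row * width + col`, with `row` counted from the top and `col` from the
#' left, both 0-based. All state indices in this package are 0-based.
#'
#' @param row 0-based row from the top (vectorised).
#' @param col 0-based column from the left (vectorised).
#' @param spec A [grid_spec()].
#'
#' @return `coord_to_state()` returns integer state indices;
#'   `state_to_coord()` returns a data frame with columns `row` and `col`.
#' @export
#' @examples
#' s5 <- grid_spec(5, 5)
#' coord_to_state(2, 2, s5)   # centre of a 5x5 grid: state 12
#' state_to_coord(12, s5)
coord_to_state <- function(row, col, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= spec$height | col < 0L | col >= spec$width))
    stop("coordinates out of range for this grid", call. = FALSE)
  row * spec$width + col
}

#' @rdname coord_to_state
#' @param state 0-based state index (vectorised).
#' @export
state_to_coord <- function(state, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  state <- as.integer(state)
  if (any(state < 0L | state >= spec$n_states))
    stop("state index out of range for this grid", call. = FALSE)
  data.frame(row = state %/% spec$width, col = state %% spec$width)
}

#' Build a cost-only tabular MDP for an empty gridworld
#'
#' Constructs the episodic, undiscounted MDP tuple for an empty rectangular
#' gridworld. Transitions are deterministic; a move off the boundary leaves
#' the agent where it is (wall bump) but still costs one step. Every
#' transition out of a transient state yields reward -1; goal states are
#' absorbing with reward 0, so the negative optimal value equals path length
#' in steps.
#'
#' @param spec A [grid_spec()].
#' @param goals Non-empty set of 0-based state indices to make absorbing.
#'
#' @return An object of class `tabular_mdp` with fields:
#'   * `n_states`, `n_actions`, `actions` — sizes and the ordered action table;
#'   * `P` — list (one per action) of sparse row-stochastic transition
#'     matrices, `P[[a]][s, s']` = probability of successor `s'`;
#'   * `succ` — deterministic successor index matrix (1-based internally);
#'   * `reward` — per-state step reward (-1 transient, 0 at goals);
#'   * `goals` — 0-based goal indices; `transient` — 1-based indices of the
#'     non-goal states; `spec` — the grid specification.
#' @export
#' @examples
#' m <- build_gridworld(grid_spec(5, 5), goals = 12)
#' m$reward[13]  # goal state 12 (1-based element 13) has step reward 0
build_gridworld <- function(spec, goals) {
  stopifnot(inherits(spec, "grid_spec"))
  goals <- unique(as.integer(goals))
  if (length(goals) == 0L) stop("`goals` must be non-empty", call. = FALSE)
  if (any(goals < 0L | goals >= spec$n_states))
    stop("goal index out of range for this grid", call. = FALSE)

  n <- spec$n_states
  acts <- spec$actions
  n_a <- nrow(acts)
  coords <- state_to_coord(seq_len(n) - 1L, spec)

  # deterministic successor of every (state, action); a move whose target
  # lies off the grid (in either coordinate) is a wall bump: the agent does
  # not move at all but still pays the step cost
  succ <- matrix(0L, n, n_a, dimnames = list(NULL, acts$action))
  for (a in seq_len(n_a)) {
    r2 <- coords$row + acts$drow[a]
    c2 <- coords$col + acts$dcol[a]
    bump <- r2 < 0L | r2 >= spec$height | c2 < 0L | c2 >= spec$width
    tgt <- r2 * spec$width + c2 + 1L
    tgt[bump] <- which(bump)
    succ[, a] <- tgt
  }
  succ[goals + 1L, ] <- goals + 1L  # absorbing

  P <- lapply(seq_len(n_a), function(a)
    Matrix::sparseMatrix(i = seq_len(n), j = succ[, a], x = 1, dims = c(n, n)))
  names(P) <- acts$action

  reward <- rep(-1, n)
  reward[goals + 1L] <- 0

  mdp <- structure(
    list(
      n_states = n,
      n_actions = n_a,
      actions = acts,
      P = P,
      # all actions stacked into one ((n * n_a) x n) operator so the solver
      # computes every expectation E[f(S') | s, a] with a single matvec
      P_stack = do.call(rbind, P),
      succ = succ,
      reward = reward,
      goals = goals,
      transient = setdiff(seq_len(n), goals + 1L),
      deterministic = TRUE,
      spec = spec
    ),
    class = "tabular_mdp"
  )
  validate_mdp(mdp)
  mdp
}

validate_mdp <- function(mdp) {
  rs <- vapply(mdp$P, function(p) range(Matrix::rowSums(p)), numeric(2))
  if (max(abs(rs - 1)) > 1e-12)
    stop("transition rows must each sum to 1", call. = FALSE)
  for (g in mdp$goals + 1L) {
    if (any(mdp$succ[g, ] != g) || mdp$reward[g] != 0)
      stop("goal states must be absorbing with zero reward", call. = FALSE)
  }
  invisible(mdp)
}

#' @export
print.tabular_mdp <- function(x, ...) {
  cat(sprintf("<tabular_mdp> %d states, %d actions (%s), goals {%s}\n",
              x$n_states, x$n_actions, x$spec$neighborhood,
              paste(x$goals, collapse = ", ")))
  invisible(x)
}

# 0-based user-facing state index -> 1-based internal row
sidx <- function(s) as.integer(s) + 1L
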