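#' Maximal covering location problem (MCLP)
#'
#' Given the binary coverage relation `a[i, j]` (candidate `j` covers
#' demand `i` within the service standard), nonnegative demand weights
#' `w_i` and a facility budget `p`, the MCLP selects sites `x_j` to
#' maximize the covered weight `sum(w_i * y_i)` subject to
#' `y_i <= sum_j a[i, j] * x_j` and `sum_j x_j <= p`. Opening fewer than
#' `p` sites is allowed when extra sites add nothing.
#'
#' @param coverage a [build_coverage_matrix()] result, or a bare 0/1 matrix
#'   with demand ids as rownames and candidate ids as colnames.
#' @param p number of facilities to open (1 <= p <= number of candidates).
#' @param weights per-demand nonnegative weights (default all 1: every
#'   simulated occurrence counts equally).
#' @return A list of class `mclp_problem` with fields `a`, `weights`, `p`,
#'   `demand_ids`, `candidate_ids`.
#' @export
mclp_problem <- function(coverage, p, weights = NULL) {
  a <- if (inherits(coverage, "coverage_matrix")) coverage$a else as.matrix(coverage)
  if (is.null(rownames(a))) rownames(a) <- sprintf("d%03d", seq_len(nrow(a)))
  if (is.null(colnames(a))) colnames(a) <- sprintf("c%03d", seq_len(ncol(a)))
  if (!all(a %in% c(0L, 1L))) stop("coverage entries must be 0/1")
  weights <- weights %||% rep(1, nrow(a))
  if (length(weights) != nrow(a)) stop("weights length must equal demand count")
  if (any(weights < 0)) stop("weights must be nonnegative")
  p <- as.integer(p)
  if (p < 1 || p > ncol(a)) stop("p must satisfy 1 <= p <= number of candidates")
  structure(list(a = a, weights = as.numeric(weights), p = p,
                 demand_ids = rownames(a), candidate_ids = colnames(a)),
            class = "mclp_problem")
}

mclp_solution <- function(problem, selected_idx, method, optimal) {
  sel <- sort(selected_idx)
  covered <- if (length(sel))
    rowSums(problem$a[, sel, drop = FALSE]) > 0 else rep(FALSE, nrow(problem$a))
  structure(list(
    selected = problem$candidate_ids[sel],
    covered = problem$demand_ids[covered],
    objective = sum(problem$weights[covered]),
    p = problem$p, method = method, optimal = optimal,
    n_demand = nrow(problem$a)), class = "mclp_solution")
}

#' @export
print.mclp_solution <- function(x, ...) {
  cat(sprintf(
    "<mclp_solution> %s%s: %d site(s) opened, objective %g (%d/%d demand covered)\n",
    x$method, if (x$optimal) " (optimal)" else "", length(x$selected),
    x$objective, length(x$covered), x$n_demand))
  cat("  sites:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Greedy MCLP solver
#'
#' Repeatedly opens the candidate covering the largest still-uncovered
#' weight, up to `p` sites or until no candidate adds anything; ties are
#' broken by the lowest candidate index. By the classical submodular
#' maximization guarantee the greedy objective is at least
#' `(1 - 1/e)` of the optimum. The solution is flagged optimal only in the
#' trivially verifiable case that it covers every demand point.
#'
#' @param problem an [mclp_problem()].
#' @return an `mclp_solution`, method `"greedy"`.
#' @export
solve_mclp_greedy <- function(problem) {
  stopifnot(inherits(problem, "mclp_problem"))
  a <- problem$a; w <- problem$weights
  uncovered <- rep(TRUE, nrow(a))
  sel <- integer(0)
  for (step in seq_len(problem$p)) {
    gain <- colSums(a * (w * uncovered))
    gain[sel] <- -1
    best <- which.max(gain)       # first maximum = lowest index tie-break
    if (gain[best] <= 0) break
    sel <- c(sel, best)
    uncovered <- uncovered & a[, best] == 0
  }
  sol <- mclp_solution(problem, sel, "greedy",
                       optimal = !any(uncovered & w > 0))
  sol
}

# Lexicographic order on sorted id vectors: shorter prefix-equal set wins.
lex_smaller <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exact MCLP solver by bounded enumeration
#'
#' Enumerates candidate subsets of size 1..p and returns a globally optimal
#' selection; among optima, the lexicographically smallest sorted set of
#' candidate ids. Refuses instances whose enumeration would exceed
#' `max_combinations` subsets — use [solve_mclp_greedy()] (or an external
#' ILP solver) for those.
#'
#' @param problem an [mclp_problem()].
#' @param max_combinations enumeration budget (default 1e6 subsets).
#' @return an `mclp_solution`, method `"exact"`, `optimal = TRUE`.
#' @export
solve_mclp_exact <- function(problem, max_combinations = 1e6) {
  stopifnot(inherits(problem, "mclp_problem"))
  a <- problem$a; w <- problem$weights
  n <- ncol(a); p <- problem$p
  total <- sum(choose(n, seq_len(p)))
  if (total > max_combinations)
    stop(sprintf(
      "enumeration of %.0f subsets exceeds max_combinations = %g; use solve_mclp_greedy() or an external ILP solver",
      total, max_combinations))
  best_obj <- -Inf
  best_sel <- integer(0)
  for (k in seq_len(p)) {
    combs <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combs))) {
      sel <- combs[, c_i]
      obj <- sum(w[rowSums(a[, sel, drop = FALSE]) > 0])
      if (obj > best_obj ||
          (obj == best_obj &&
             lex_smaller(problem$candidate_ids[sel],
                         problem$candidate_ids[best_sel]))) {
        best_obj <- obj
        best_sel <- sel
      }
    }
  }
  mclp_solution(problem, best_sel, "exact", optimal = TRUE)
}

#' Smallest facility budget reaching a coverage target
#'
#' Searches p = 1, 2, ... for the smallest budget whose solution covers at
#' least `target_fraction` of the total demand weight — the workflow that
#' asks "how many AEDs are needed for the observed coverage?". If even
#' opening every candidate cannot reach the target, the best attainable
#' solution is returned with `target_met = FALSE`.
#'
#' @param coverage a [build_coverage_matrix()] result or 0/1 matrix.
#' @param target_fraction required covered fraction of total weight
#'   (0 < f <= 1).
#' @param solver `"greedy"` or `"exact"`.
#' @param weights optional per-demand weights.
#' @param ... passed to the solver.
#' @return list with `p_star`, `solution`, `target_met`.
#' @export
min_facilities_for_target <- function(coverage, target_fraction,
                                      solver = c("greedy", "exact"),
                                      weights = NULL, ...) {
  solver <- match.arg(solver)
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  a <- if (inherits(coverage, "coverage_matrix")) coverage$a else as.matrix(coverage)
  w <- weights %||% rep(1, nrow(a))
  need <- target_fraction * sum(w)
  fn <- switch(solver, greedy = solve_mclp_greedy, exact = solve_mclp_exact)
  best <- NULL
  for (p in seq_len(ncol(a))) {
    sol <- fn(mclp_problem(coverage, p, weights), ...)
    best <- sol
    if (sol$objective >= need - 1e-9)
      return(list(p_star = p, solution = sol, target_met = TRUE))
  }
  list(p_star = ncol(a), solution = best, target_met = FALSE)
}

#' Write an MCLP solution as a structured text report
#'
#' @param solution an `mclp_solution`.
#' @param path file path.
#' @export
write_mclp_report <- function(solution, path) {
  lines <- c(
    sprintf("method: %s", solution$method),
    sprintf("optimal: %s", tolower(as.character(solution$optimal))),
    sprintf("p: %d", solution$p),
    sprintf("sites_opened: %d", length(solution$selected)),
    sprintf("objective: %g", solution$objective),
    sprintf("selected: %s", paste(solution$selected, collapse = ",")),
    sprintf("covered: %s", paste(solution$covered, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
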