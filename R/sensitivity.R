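#' Specify a one-way sensitivity parameter
#'
#' Describes a single model quantity to sweep: the initial population, one
#' outcome edge's probability, or one task's per-resource duration.
#'
#' @param kind `"population"`, `"branch_probability"` or `"task_duration"`.
#' @param grid Strictly increasing numeric vector of parameter values.
#'   Branch grids must lie in `[0, 1]`; duration grids must be >= 0.
#' @param task_id Target task (branch and duration kinds).
#' @param branch_next_id Target outcome edge, identified by the task it
#'   leads to (branch kind).
#' @param resource_id Target resource (duration kind).
#' @return A `param_spec` list.
#' @seealso [sweep_parameter()]
#' @export
param_spec <- function(kind = c("population", "branch_probability", "task_duration"),
                       grid, task_id = NULL, branch_next_id = NULL,
                       resource_id = NULL) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing with at least two values",
         call. = FALSE)
  }
  if (kind == "branch_probability") {
    if (is.null(task_id) || is.null(branch_next_id)) {
      stop("branch sweeps need `task_id` and `branch_next_id`", call. = FALSE)
    }
    if (any(grid < 0 | grid > 1)) {
      stop("branch probability grid must lie in [0, 1]", call. = FALSE)
    }
  }
  if (kind == "task_duration") {
    if (is.null(task_id) || is.null(resource_id)) {
      stop("duration sweeps need `task_id` and `resource_id`", call. = FALSE)
    }
    if (any(grid < 0)) stop("durations must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, grid = grid,
                 task_id = if (is.null(task_id)) NULL else as.character(task_id),
                 branch_next_id = if (is.null(branch_next_id)) NULL else
                   as.character(branch_next_id),
                 resource_id = if (is.null(resource_id)) NULL else
                   as.character(resource_id)),
            class = "param_spec")
}

# Build the model perturbed to parameter value `value` under `spec`.
# Branch kind: the target edge gets probability p; sibling edges are scaled
# proportionally so the task's outcomes still sum to 1 (preserving the
# relative mix of the non-swept outcomes). When the siblings originally
# carry zero mass, the remaining 1 - p is split equally among them.
perturb_model <- function(m, spec, value) {
  switch(spec$kind,
    population = {
      m$population <- value
      m
    },
    task_duration = {
      t <- m$tasks[[spec$task_id]]
      if (is.null(t)) stop("unknown task: ", spec$task_id, call. = FALSE)
      if (!(spec$resource_id %in% m$resources$id)) {
        stop("unknown resource: ", spec$resource_id, call. = FALSE)
      }
      t$minutes[spec$resource_id] <- value
      m$tasks[[spec$task_id]] <- t
      m
    },
    branch_probability = {
      t <- m$tasks[[spec$task_id]]
      if (is.null(t)) stop("unknown task: ", spec$task_id, call. = FALSE)
      k <- which(t$outcomes$next_id == spec$branch_next_id)
      if (length(k) != 1L) {
        stop("task ", spec$task_id, " has no outcome edge to ",
             spec$branch_next_id, call. = FALSE)
      }
      if (nrow(t$outcomes) < 2L) {
        stop("cannot sweep the only outcome of task ", spec$task_id,
             ": sibling edges must absorb the remaining probability",
             call. = FALSE)
      }
      p0 <- t$outcomes$probability[k]
      sib_mass <- 1 - p0
      p <- t$outcomes$probability
      p[k] <- value
      if (sib_mass > 0) {
        p[-k] <- t$outcomes$probability[-k] * (1 - value) / sib_mass
      } else {
        p[-k] <- (1 - value) / (nrow(t$outcomes) - 1L)
      }
      t$outcomes$probability <- p
      m$tasks[[spec$task_id]] <- t
      m
    })
}

#' Sweep one parameter and trace each resource's FTE curve
#'
#' Evaluates [compute_flow()] at every grid value of a [param_spec()],
#' recording each resource's FTE requirement, the dominant (arg-max)
#' resource at each grid point, and all crossover points — the exact
#' parameter values at which the resource ranking changes. Because the
#' flow is affine in any single swept parameter, the traced curves are
#' exactly straight lines and crossovers are solved in closed form.
#'
#' Defaults for the packaged VA model's three standard experiments:
#' population 75,000 to 300,000 in steps of 25,000; acceptance probability
#' (task 2's edge to task 5) 0 to 1 in steps of 0.05; task 1 NN duration
#' 0 to 3 minutes in steps of 0.5.
#'
#' @param m A valid `process_map`.
#' @param spec A [param_spec()].
#' @param fte_basis_minutes Minutes per FTE unit (default 2400).
#' @param horizon_weeks Planning horizon in weeks (default 1).
#' @return A `sweep_result`: list with `spec`, `grid`, `fte_curves` (matrix,
#'   one row per grid point, one column per resource), `dominant` (character
#'   vector), `crossovers` (data frame, see [find_crossovers()]), and the
#'   model and conversion settings needed to re-evaluate points.
#' @examples
#' m <- build_va_demo()
#' sw <- sweep_parameter(m, param_spec("branch_probability",
#'   grid = seq(0, 1, by = 0.05), task_id = 2, branch_next_id = 5))
#' sw$crossovers
#' @export
sweep_parameter <- function(m, spec, fte_basis_minutes = 2400,
                            horizon_weeks = 1) {
  stop_if_invalid(m)
  stopifnot(inherits(spec, "param_spec"))
  resource_ids <- m$resources$id
  curves <- matrix(NA_real_, nrow = length(spec$grid),
                   ncol = length(resource_ids),
                   dimnames = list(NULL, resource_ids))
  for (i in seq_along(spec$grid)) {
    mi <- perturb_model(m, spec, spec$grid[i])
    fl <- compute_flow(mi, fte_basis_minutes = fte_basis_minutes,
                       horizon_weeks = horizon_weeks)
    curves[i, ] <- fl$fte[resource_ids]
  }
  dominant <- vapply(seq_along(spec$grid), function(i) {
    dominant_resource(curves[i, ])
  }, character(1))
  out <- structure(
    list(spec = spec, grid = spec$grid, fte_curves = curves,
         dominant = dominant, crossovers = NULL,
         model = m, fte_basis_minutes = fte_basis_minutes,
         horizon_weeks = horizon_weeks),
    class = "sweep_result"
  )
  out$crossovers <- find_crossovers(out)
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> kind ", x$spec$kind, ", ", length(x$grid),
      " grid points over [", x$grid[1], ", ", x$grid[length(x$grid)], "]\n",
      sep = "")
  if (nrow(x$crossovers)) {
    cat("  crossovers:\n")
    print(x$crossovers, row.names = FALSE)
  } else {
    cat("  no ranking changes along the sweep\n")
  }
  invisible(x)
}

#' Locate exact resource-ranking crossovers along a sweep
#'
#' For every pair of resources whose FTE difference changes sign between
#' adjacent grid points, solves the intersection from the affine segment.
#' Single-parameter flows are exactly affine, so the linear solve is exact,
#' not an approximation; each solution is confirmed by re-evaluating the
#' flow at the solved parameter (the two FTEs agree to 1e-9 there).
#' Crossovers sitting exactly on an interior grid point are reported once.
#'
#' @param sweep A `sweep_result`.
#' @return A data frame sorted by parameter value with columns `param`
#'   (crossing parameter), `overtaken` (resource that was higher before),
#'   `overtaking` (resource higher after) and `fte` (shared FTE value at
#'   the intersection). Empty when the ranking never changes.
#' @export
find_crossovers <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  grid <- sweep$grid
  curves <- sweep$fte_curves
  res <- colnames(curves)
  rows <- list()
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (a >= b) next
      d <- curves[, a] - curves[, b]
      for (i in seq_len(length(grid) - 1L)) {
        d_lo <- d[i]; d_hi <- d[i + 1L]
        p_star <- NA_real_
        if (d_lo * d_hi < 0) {
          p_star <- grid[i] + d_lo / (d_lo - d_hi) * (grid[i + 1L] - grid[i])
        } else if (d_lo == 0 && i > 1L && d[i - 1L] * d_hi < 0) {
          p_star <- grid[i]  # ranking flips exactly at an interior grid point
        }
        if (is.na(p_star)) next
        fte_star <- eval_sweep_point(sweep, p_star)
        before <- if (d_lo != 0) d_lo > 0 else d[i - 1L] > 0
        rows[[length(rows) + 1L]] <- data.frame(
          param = p_star,
          overtaken = if (before) res[a] else res[b],
          overtaking = if (before) res[b] else res[a],
          fte = mean(fte_star[c(res[a], res[b])]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(param = numeric(0), overtaken = character(0),
                      overtaking = character(0), fte = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("param", "overtaken", "overtaking")]), ,
             drop = FALSE]
  out <- out[order(out$param), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Re-evaluate the swept model's FTE vector at an arbitrary parameter value.
eval_sweep_point <- function(sweep, value) {
  mi <- perturb_model(sweep$model, sweep$spec, value)
  compute_flow(mi, fte_basis_minutes = sweep$fte_basis_minutes,
               horizon_weeks = sweep$horizon_weeks)$fte
}

#' The resource requiring the most FTEs
#'
#' @param fte Named numeric vector of FTEs by resource.
#' @return The arg-max resource id. Exact ties are broken by lexicographic
#'   resource id and flagged with attribute `tie = TRUE`.
#' @examples
#' dominant_resource(compute_flow(build_va_demo())$fte)
#' @export
dominant_resource <- function(fte) {
  if (!length(fte) || is.null(names(fte))) {
    stop("`fte` must be a non-empty named vector", call. = FALSE)
  }
  top <- max(fte)
  winners <- sort(names(fte)[fte == top], method = "radix")
  structure(winners[1L], tie = length(winners) > 1L)
}
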