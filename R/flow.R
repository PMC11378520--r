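#' Deterministic topological order of a process map
#'
#' Kahn's algorithm with ties broken by ascending task id (numerically when
#' every id is a number, lexicographically otherwise). Every edge goes from
#' an earlier to a later position. The acyclicity assumption — patients
#' progress step-wise and never repeat a task — guarantees the order exists;
#' a cycle is re-checked defensively and raises an error.
#'
#' @param m A valid `process_map`.
#' @return Character vector of task ids.
#' @export
topological_order <- function(m) {
  stopifnot(inherits(m, "process_map"))
  ids <- names(m$tasks)
  edges <- model_edges(m)
  indeg <- table(factor(edges$to, levels = ids))
  ready <- order_task_ids(ids[indeg[ids] == 0L])
  out <- character(0)
  while (length(ready)) {
    cur <- ready[[1L]]
    ready <- ready[-1L]
    out <- c(out, cur)
    for (nxt in m$tasks[[cur]]$outcomes$next_id) {
      indeg[nxt] <- indeg[nxt] - 1L
      if (indeg[nxt] == 0L) ready <- order_task_ids(c(ready, nxt))
    }
  }
  if (length(out) != length(ids)) {
    stop("cycle detected; topological order does not exist", call. = FALSE)
  }
  out
}

#' Propagate expected patient flow and aggregate resource needs
#'
#' The core expected-value computation. Patients enter at the root and are
#' split down outcome edges by their probabilities, so the expected number
#' of patients at a task is the probability-weighted sum over its incoming
#' edges, computed in a single pass in topological order. Per-resource
#' totals are the sum over tasks of (expected patients at the task) x
#' (minutes per patient the task consumes of that resource), and full-time
#' equivalents (FTEs) divide total minutes by the minutes one full-time
#' person works over the planning horizon.
#'
#' Expected counts are continuous — a 0.5% branch sends 0.005 of a patient —
#' because the computation is an expectation, never rounded. Consequently
#' every output is exactly linear in the population and affine in any single
#' task duration or (after renormalisation) branch probability; the
#' sensitivity module relies on this.
#'
#' @param m A valid `process_map`.
#' @param population Patients entering at the root; defaults to the model's
#'   `population`. Must be non-negative.
#' @param fte_basis_minutes Minutes of work that define one FTE-week.
#'   Default 2400 = 40 hours x 60, i.e. one person's 40-hour week.
#' @param horizon_weeks Planning horizon in 40-hour weeks; FTEs are divided
#'   by it (2 people working one week equal 1 person working two weeks).
#' @return A `flow_result`: list with `expected_count` (named by task id),
#'   `total_minutes` and `fte` (named by resource id), plus the inputs
#'   (`population`, `fte_basis_minutes`, `horizon_weeks`).
#' @examples
#' fl <- compute_flow(build_va_demo())
#' fl$fte
#' @export
compute_flow <- function(m, population = NULL,
                         fte_basis_minutes = 2400, horizon_weeks = 1) {
  stop_if_invalid(m)
  if (is.null(population)) population <- m$population
  stopifnot(is.numeric(population), length(population) == 1L)
  if (population < 0) stop("`population` must be non-negative", call. = FALSE)
  if (fte_basis_minutes <= 0) stop("`fte_basis_minutes` must be positive",
                                   call. = FALSE)
  if (horizon_weeks <= 0) stop("`horizon_weeks` must be positive", call. = FALSE)

  topo <- topological_order(m)
  count <- stats::setNames(numeric(length(topo)), topo)
  count[m$root] <- population
  for (id in topo) {
    t <- m$tasks[[id]]
    if (nrow(t$outcomes)) {
      flows <- count[id] * t$outcomes$probability
      for (k in seq_along(flows)) {
        nxt <- t$outcomes$next_id[k]
        count[nxt] <- count[nxt] + flows[k]
      }
    }
  }

  resource_ids <- m$resources$id
  total <- stats::setNames(numeric(length(resource_ids)), resource_ids)
  for (id in topo) {
    mins <- m$tasks[[id]]$minutes
    if (length(mins)) total[names(mins)] <- total[names(mins)] + count[id] * mins
  }

  structure(
    list(expected_count = count[order_task_ids(names(count))],
         total_minutes = total,
         fte = total / (fte_basis_minutes * horizon_weeks),
         population = population,
         fte_basis_minutes = fte_basis_minutes,
         horizon_weeks = horizon_weeks),
    class = "flow_result"
  )
}

#' @export
print.flow_result <- function(x, ...) {
  cat("<flow_result> population ", format(x$population, big.mark = ","),
      ", FTE basis ", x$fte_basis_minutes, " min/week, horizon ",
      x$horizon_weeks, " week(s)\n", sep = "")
  tab <- data.frame(resource = names(x$total_minutes),
                    minutes = round(x$total_minutes, 4),
                    fte = round(x$fte, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Convert minutes of work to full-time equivalents
#'
#' @param minutes Non-negative total minutes.
#' @param fte_basis_minutes Minutes per FTE unit (default 2400, one 40-hour
#'   week).
#' @return `minutes / fte_basis_minutes`.
#' @examples
#' minutes_to_fte(2400)    # 1
#' minutes_to_fte(131400)  # 54.75
#' @export
minutes_to_fte <- function(minutes, fte_basis_minutes = 2400) {
  if (any(fte_basis_minutes <= 0)) stop("`fte_basis_minutes` must be positive",
                                        call. = FALSE)
  minutes / fte_basis_minutes
}

#' Enumerate every root-to-terminal path (brute-force oracle)
#'
#' Exhaustively lists all paths a patient can take through the graph, with
#' each path's probability (product of its branch probabilities) and the
#' per-resource minutes accumulated along it. Summing population x path
#' probability x path minutes over all paths must reproduce
#' [compute_flow()]'s totals; the path table therefore serves as an
#' independent check of the single-pass propagation. Guarded at
#' `max_paths` paths since path counts can grow exponentially.
#'
#' @param m A valid `process_map`.
#' @param population Patients entering at the root (defaults to the model's).
#' @param max_paths Abort if the enumeration exceeds this many paths.
#' @return A `path_table`: list with `paths` (list of task-id vectors),
#'   `probability`, `minutes` (matrix, one row per path, one column per
#'   resource), `total_minutes` (population-weighted totals) and
#'   `population`.
#' @export
enumerate_paths <- function(m, population = NULL, max_paths = 10000) {
  stop_if_invalid(m)
  if (is.null(population)) population <- m$population
  resource_ids <- m$resources$id

  paths <- list()
  probs <- numeric(0)
  mins <- list()

  walk <- function(id, path, p, acc) {
    t <- m$tasks[[id]]
    acc <- acc + resolved_minutes(t, resource_ids)
    path <- c(path, id)
    if (nrow(t$outcomes) == 0L) {
      if (length(paths) + 1L > max_paths) {
        stop("path enumeration exceeded ", max_paths, " paths", call. = FALSE)
      }
      paths[[length(paths) + 1L]] <<- path
      probs[length(probs) + 1L] <<- p
      mins[[length(mins) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (k in seq_len(nrow(t$outcomes))) {
      walk(t$outcomes$next_id[k], path, p * t$outcomes$probability[k], acc)
    }
  }
  walk(m$root, character(0), 1,
       stats::setNames(numeric(length(resource_ids)), resource_ids))

  minutes <- do.call(rbind, mins)
  colnames(minutes) <- resource_ids
  total <- colSums(minutes * probs) * population
  structure(
    list(paths = paths, probability = probs, minutes = minutes,
         total_minutes = total, population = population),
    class = "path_table"
  )
}

#' @export
print.path_table <- function(x, ...) {
  cat("<path_table> ", length(x$paths), " root-to-terminal paths, population ",
      format(x$population, big.mark = ","), "\n", sep = "")
  cat("  probability sum:", format(sum(x$probability), digits = 12), "\n")
  invisible(x)
}
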