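#' Build a process-map model of a screening program
#'
#' A process map is a directed acyclic graph of program steps ("tasks").
#' Each task consumes a fixed number of minutes of named human resources per
#' patient who reaches it, and routes patients to subsequent tasks with
#' stated probabilities. A single root task is the program entry point;
#' patients flow until they reach a terminal task (one with no outcomes).
#'
#' @param resources A character vector of resource ids, or a data frame with
#'   columns `id` and `description`.
#' @param tasks A list of tasks created with [task()].
#' @param root The id of the entry task. If `NULL`, the unique task with no
#'   incoming edges is used.
#' @param population Initial population entering at the root. May be
#'   overridden at run time by [compute_flow()].
#'
#' @return An object of class `process_map` with elements `resources`
#'   (data frame), `tasks` (named list keyed by task id), `root` and
#'   `population`.
#' @seealso [task()], [branch()], [validate_model()], [build_va_demo()]
#' @examples
#' m <- process_map(
#'   resources = "Nurse",
#'   tasks = list(
#'     task(1, "triage", minutes = c(Nurse = 5),
#'          outcomes = list(branch(2, 1))),
#'     task(2, "done")
#'   ),
#'   population = 100
#' )
#' compute_flow(m)
#' @export
process_map <- function(resources, tasks, root = NULL, population = 0) {
  resources <- as_resource_frame(resources)
  if (!is.list(tasks) || length(tasks) == 0L) {
    stop("`tasks` must be a non-empty list of task() objects", call. = FALSE)
  }
  tasks <- lapply(tasks, as_task)
  ids <- vapply(tasks, function(t) t$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate task id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(tasks) <- ids
  if (is.null(root)) {
    root <- infer_root(tasks)
  }
  root <- as.character(root)
  if (!is.numeric(population) || length(population) != 1L || is.na(population)) {
    stop("`population` must be a single number", call. = FALSE)
  }
  structure(
    list(resources = resources, tasks = tasks, root = root,
         population = as.numeric(population)),
    class = "process_map"
  )
}

#' Define one task of a process map
#'
#' @param id Task identifier (coerced to character; integers in the packaged
#'   fixture). Ids are opaque labels: no ordering is assumed from them.
#' @param label Free-text description of the step.
#' @param minutes Named numeric vector mapping resource ids to non-negative
#'   minutes-per-patient. Resources not named consume zero minutes.
#' @param outcomes A list of [branch()] objects (or a data frame with columns
#'   `next_id` and `probability`). Empty or `NULL` marks a terminal task.
#' @return A `sf_task` list with normalised fields.
#' @export
task <- function(id, label = "", minutes = NULL, outcomes = NULL) {
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("task `id` must be a single non-empty value", call. = FALSE)
  }
  if (is.null(minutes)) minutes <- numeric(0)
  if (length(minutes) && is.null(names(minutes))) {
    stop("`minutes` must be a named numeric vector (resource id -> minutes)",
         call. = FALSE)
  }
  minutes <- vapply(minutes, as.numeric, numeric(1))
  outcomes <- as_outcome_frame(outcomes)
  structure(list(id = id, label = as.character(label), minutes = minutes,
                 outcomes = outcomes),
            class = "sf_task")
}

#' Define one outcome edge of a task
#'
#' @param next_id Id of the task patients move to.
#' @param probability Fraction of patients taking this edge, in `[0, 1]`.
#'   Probabilities of all outcomes of a task must sum to 1.
#' @return A one-row data frame with columns `next_id` and `probability`.
#' @export
branch <- function(next_id, probability) {
  data.frame(next_id = as.character(next_id),
             probability = as.numeric(probability),
             stringsAsFactors = FALSE)
}

as_resource_frame <- function(resources) {
  if (is.character(resources)) {
    resources <- data.frame(id = resources, description = "",
                            stringsAsFactors = FALSE)
  }
  if (!is.data.frame(resources) || !all(c("id") %in% names(resources))) {
    stop("`resources` must be a character vector or a data frame with an `id` column",
         call. = FALSE)
  }
  if (is.null(resources$description)) resources$description <- ""
  resources$id <- as.character(resources$id)
  resources$description <- as.character(resources$description)
  if (any(!nzchar(resources$id)) || anyNA(resources$id)) {
    stop("resource ids must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(resources$id)) {
    stop("duplicate resource id(s): ",
         paste(unique(resources$id[duplicated(resources$id)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(resources) <- NULL
  resources[c("id", "description")]
}

as_task <- function(t) {
  if (inherits(t, "sf_task")) return(t)
  stop("`tasks` entries must be created with task()", call. = FALSE)
}

as_outcome_frame <- function(outcomes) {
  if (is.null(outcomes) || (is.data.frame(outcomes) && nrow(outcomes) == 0L) ||
      (is.list(outcomes) && length(outcomes) == 0L)) {
    return(data.frame(next_id = character(0), probability = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(outcomes)) {
    out <- outcomes
  } else {
    out <- do.call(rbind, outcomes)
  }
  if (!all(c("next_id", "probability") %in% names(out))) {
    stop("outcomes need columns `next_id` and `probability`", call. = FALSE)
  }
  out$next_id <- as.character(out$next_id)
  out$probability <- as.numeric(out$probability)
  rownames(out) <- NULL
  out[c("next_id", "probability")]
}

infer_root <- function(tasks) {
  has_incoming <- unique(unlist(lapply(tasks, function(t) t$outcomes$next_id)))
  roots <- setdiff(names(tasks), has_incoming)
  if (length(roots) != 1L) {
    stop("cannot infer a unique root task (candidates: ",
         paste(roots, collapse = ", "), "); pass `root` explicitly",
         call. = FALSE)
  }
  roots
}

#' @export
print.process_map <- function(x, ...) {
  cat("<process_map>\n")
  cat("  tasks:     ", length(x$tasks), " (root ", x$root,
      ", terminal ", paste(terminal_tasks(x), collapse = ", "), ")\n", sep = "")
  cat("  resources: ", paste(x$resources$id, collapse = ", "), "\n", sep = "")
  cat("  population:", format(x$population, big.mark = ","), "\n")
  invisible(x)
}

# Task ids with no outcomes (program exits).
#' Terminal tasks of a model
#' @param m A `process_map`.
#' @return Character vector of task ids with no outcome edges.
#' @export
terminal_tasks <- function(m) {
  ids <- names(m$tasks)
  ids[vapply(m$tasks, function(t) nrow(t$outcomes) == 0L, logical(1))]
}

# Edge list view of the graph: one row per outcome edge.
model_edges <- function(m) {
  rows <- lapply(m$tasks, function(t) {
    if (nrow(t$outcomes) == 0L) return(NULL)
    data.frame(from = t$id, to = t$outcomes$next_id,
               probability = t$outcomes$probability,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(from = character(0), to = character(0),
                      probability = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Order task ids ascending: numerically when all ids are numeric labels,
# lexicographically otherwise. Used for deterministic tie-breaking.
order_task_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else sort(ids, method = "radix")
}

#' Validate the structural invariants of a process map
#'
#' Checks the assumptions the flow engine relies on: a single entry task,
#' an acyclic graph (patients never repeat a step), outcome probabilities
#' that sum to one at every non-terminal task, non-negative task minutes,
#' resolvable edge targets, declared resources and at least one terminal
#' task. All violations are collected and returned; nothing is thrown.
#'
#' Error codes: `CYCLE`, `BAD_PROB_SUM`, `PROB_RANGE`, `UNKNOWN_NEXT_ID`,
#' `NEGATIVE_MINUTES`, `UNKNOWN_RESOURCE`, `MULTIPLE_ROOTS`, `ROOT_MISMATCH`,
#' `NO_TERMINAL`, `BAD_POPULATION`. Warning code: `UNREACHABLE_TASK`
#' (a warning, not an error: unreachable tasks carry zero flow).
#'
#' Probability sums are checked to a tolerance of 1e-6 and are never silently
#' renormalised; a planning tool should surface authoring errors.
#'
#' @param m A `process_map`.
#' @return A `validation_report`: list with data frames `errors` and
#'   `warnings`, each with columns `code`, `task_id`, `message`.
#' @examples
#' report <- validate_model(build_va_demo())
#' nrow(report$errors)  # 0
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "process_map"))
  errors <- list()
  warnings <- list()
  note <- function(code, task_id, message) {
    data.frame(code = code, task_id = task_id, message = message,
               stringsAsFactors = FALSE)
  }

  ids <- names(m$tasks)
  resource_ids <- m$resources$id

  for (t in m$tasks) {
    bad_res <- setdiff(names(t$minutes), resource_ids)
    if (length(bad_res)) {
      errors <- c(errors, list(note("UNKNOWN_RESOURCE", t$id,
        paste0("task ", t$id, " uses undeclared resource(s): ",
               paste(bad_res, collapse = ", ")))))
    }
    if (any(t$minutes < 0)) {
      errors <- c(errors, list(note("NEGATIVE_MINUTES", t$id,
        paste0("task ", t$id, " has negative minutes"))))
    }
    if (nrow(t$outcomes)) {
      p <- t$outcomes$probability
      if (any(p < 0 | p > 1)) {
        errors <- c(errors, list(note("PROB_RANGE", t$id,
          paste0("task ", t$id, " has branch probabilities outside [0, 1]"))))
      }
      if (abs(sum(p) - 1) > 1e-6) {
        errors <- c(errors, list(note("BAD_PROB_SUM", t$id,
          sprintf("task %s outcome probabilities sum to %.9g, not 1",
                  t$id, sum(p)))))
      }
      missing <- setdiff(t$outcomes$next_id, ids)
      if (length(missing)) {
        errors <- c(errors, list(note("UNKNOWN_NEXT_ID", t$id,
          paste0("task ", t$id, " routes to unknown task(s): ",
                 paste(missing, collapse = ", ")))))
      }
    }
  }

  edges <- model_edges(m)
  edges <- edges[edges$to %in% ids, , drop = FALSE]
  roots <- setdiff(ids, unique(edges$to))
  if (length(roots) > 1L) {
    errors <- c(errors, list(note("MULTIPLE_ROOTS", paste(roots, collapse = ","),
      paste0("more than one entry task (no incoming edges): ",
             paste(order_task_ids(roots), collapse = ", ")))))
  }
  if (!(m$root %in% ids)) {
    errors <- c(errors, list(note("ROOT_MISMATCH", m$root,
      paste0("declared root ", m$root, " is not a task"))))
  } else if (length(roots) >= 1L && !(m$root %in% roots)) {
    errors <- c(errors, list(note("ROOT_MISMATCH", m$root,
      paste0("declared root ", m$root, " has incoming edges"))))
  }

  if (length(terminal_tasks(m)) == 0L) {
    errors <- c(errors, list(note("NO_TERMINAL", NA_character_,
      "model has no terminal task; patients can never complete")))
  }

  # Kahn peel: anything left has an incoming edge from inside the remainder,
  # i.e. sits on (or downstream inside) a cycle.
  indeg <- table(factor(edges$to, levels = ids))
  remaining <- ids
  repeat {
    zero <- remaining[indeg[remaining] == 0L]
    if (!length(zero)) break
    remaining <- setdiff(remaining, zero)
    out_edges <- edges[edges$from %in% zero, , drop = FALSE]
    if (nrow(out_edges)) {
      drop <- table(factor(out_edges$to, levels = ids))
      indeg <- indeg - drop
    }
  }
  if (length(remaining)) {
    errors <- c(errors, list(note("CYCLE", paste(remaining, collapse = ","),
      paste0("cycle detected involving task(s): ",
             paste(order_task_ids(remaining), collapse = ", ")))))
  }

  if (m$population < 0) {
    errors <- c(errors, list(note("BAD_POPULATION", NA_character_,
      "initial population is negative")))
  }

  if (m$root %in% ids && !length(remaining)) {
    reached <- reachable_from(m, m$root)
    unreachable <- setdiff(ids, reached)
    if (length(unreachable)) {
      warnings <- c(warnings, list(note("UNREACHABLE_TASK",
        paste(unreachable, collapse = ","),
        paste0("task(s) unreachable from root: ",
               paste(order_task_ids(unreachable), collapse = ", ")))))
    }
  }

  empty <- data.frame(code = character(0), task_id = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  structure(
    list(errors = if (length(errors)) do.call(rbind, errors) else empty,
         warnings = if (length(warnings)) do.call(rbind, warnings) else empty),
    class = "validation_report"
  )
}

reachable_from <- function(m, start) {
  seen <- character(0)
  stack <- start
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    nxt <- m$tasks[[cur]]$outcomes$next_id
    stack <- c(stack, setdiff(nxt, seen))
  }
  seen
}

#' Does a model (or a validation report) pass validation?
#' @param x A `process_map` or a `validation_report`.
#' @return `TRUE` when there are no errors (warnings are allowed).
#' @export
is_valid <- function(x) {
  if (inherits(x, "process_map")) x <- validate_model(x)
  stopifnot(inherits(x, "validation_report"))
  nrow(x$errors) == 0L
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  if (nrow(x$errors)) {
    for (i in seq_len(nrow(x$errors)))
      cat("  ERROR [", x$errors$code[i], "] ", x$errors$message[i], "\n", sep = "")
  }
  if (nrow(x$warnings)) {
    for (i in seq_len(nrow(x$warnings)))
      cat("  warning [", x$warnings$code[i], "] ", x$warnings$message[i], "\n",
          sep = "")
  }
  invisible(x)
}

# Downstream operations refuse models with validation errors.
stop_if_invalid <- function(m) {
  report <- validate_model(m)
  if (nrow(report$errors)) {
    stop("invalid process map:\n  ",
         paste(sprintf("[%s] %s", report$errors$code, report$errors$message),
               collapse = "\n  "),
         call. = FALSE)
  }
  invisible(report)
}

#' Compare two process maps for equality
#'
#' Structure (task ids, resource ids, edges) is compared exactly; minutes
#' and branch probabilities to a numeric tolerance. Free-text fields
#' (labels, resource descriptions) are ignored, so a model survives a
#' round-trip through the CSV dialect, which does not carry descriptions.
#'
#' @param a,b Process maps.
#' @param tol Numeric tolerance for minutes and probabilities.
#' @return `TRUE` or `FALSE`.
#' @export
model_equal <- function(a, b, tol = 1e-12) {
  if (!setequal(names(a$tasks), names(b$tasks))) return(FALSE)
  if (!setequal(a$resources$id, b$resources$id)) return(FALSE)
  if (a$root != b$root) return(FALSE)
  if (abs(a$population - b$population) > tol) return(FALSE)
  for (id in names(a$tasks)) {
    ta <- a$tasks[[id]]; tb <- b$tasks[[id]]
    ra <- resolved_minutes(ta, a$resources$id)
    rb <- resolved_minutes(tb, a$resources$id)
    if (any(abs(ra - rb) > tol)) return(FALSE)
    if (nrow(ta$outcomes) != nrow(tb$outcomes)) return(FALSE)
    if (nrow(ta$outcomes)) {
      if (!identical(ta$outcomes$next_id, tb$outcomes$next_id)) return(FALSE)
      if (any(abs(ta$outcomes$probability - tb$outcomes$probability) > tol))
        return(FALSE)
    }
  }
  TRUE
}

# Minutes vector of a task over the full resource set, zeros filled in.
resolved_minutes <- function(t, resource_ids) {
  out <- stats::setNames(numeric(length(resource_ids)), resource_ids)
  if (length(t$minutes)) out[names(t$minutes)] <- t$minutes
  out
}
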