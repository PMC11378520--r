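#' Build a structured run report for a model
#'
#' One self-contained record of a planning run: a model summary, the
#' analytic flow, a per-task table showing each task's expected patient
#' count and the minutes it contributes to every resource, the FTE ranking
#' (dominant resource first), and a provenance block carrying everything
#' needed to reproduce the run (model content hash, parameters, package
#' version). The per-task minute contributions sum to the flow's
#' per-resource totals by construction.
#'
#' @param m A valid `process_map`.
#' @param population Patients entering at the root (defaults to the
#'   model's).
#' @param fte_basis_minutes Minutes per FTE-week (default 2400).
#' @param horizon_weeks Planning horizon in weeks (default 1); FTEs are
#'   divided by it.
#' @return A `run_report`: list with `summary`, `flow` (a `flow_result`),
#'   `per_task` (data frame), `ranking` (data frame, FTE-descending) and
#'   `provenance`.
#' @examples
#' run_report(build_va_demo())
#' @export
run_report <- function(m, population = NULL, fte_basis_minutes = 2400,
                       horizon_weeks = 1) {
  stop_if_invalid(m)
  flow <- compute_flow(m, population = population,
                       fte_basis_minutes = fte_basis_minutes,
                       horizon_weeks = horizon_weeks)
  resource_ids <- m$resources$id
  ord <- order_task_ids(names(m$tasks))

  per_task <- data.frame(
    task_id = ord,
    label = vapply(ord, function(id) m$tasks[[id]]$label, character(1)),
    expected_count = unname(flow$expected_count[ord]),
    stringsAsFactors = FALSE
  )
  for (r in resource_ids) {
    per_task[[paste0("minutes_", r)]] <- vapply(ord, function(id) {
      unname(resolved_minutes(m$tasks[[id]], resource_ids)[r]) *
        flow$expected_count[[id]]
    }, numeric(1))
  }

  fte_sorted <- sort(flow$fte, decreasing = TRUE)
  # stable ordering among exact ties: lexicographic id
  fte_sorted <- fte_sorted[order(-fte_sorted, names(fte_sorted),
                                 method = "radix")]
  ranking <- data.frame(resource = names(fte_sorted),
                        total_minutes = unname(flow$total_minutes[names(fte_sorted)]),
                        fte = unname(fte_sorted),
                        stringsAsFactors = FALSE)
  tie <- anyDuplicated(ranking$fte) > 0L

  structure(
    list(summary = list(n_tasks = length(m$tasks),
                        n_resources = length(resource_ids),
                        root = m$root,
                        terminals = terminal_tasks(m)),
         flow = flow,
         per_task = per_task,
         ranking = ranking,
         tie = tie,
         provenance = list(model_hash = model_hash(m),
                           population = flow$population,
                           fte_basis_minutes = fte_basis_minutes,
                           horizon_weeks = horizon_weeks,
                           package_version =
                             as.character(utils::packageVersion("screenflow")))),
    class = "run_report"
  )
}

# md5 of the canonical CSV serialisation: identifies model content, not the
# file it came from.
model_hash <- function(m) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(write_model_csv(m), tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$summary$n_tasks, " tasks, ",
      x$summary$n_resources, " resources, population ",
      format(x$flow$population, big.mark = ","), "\n", sep = "")
  cat("  FTE ranking (basis ", x$flow$fte_basis_minutes, " min, horizon ",
      x$flow$horizon_weeks, " week(s))",
      if (isTRUE(x$tie)) " [tie]" else "", ":\n", sep = "")
  tab <- x$ranking
  tab$total_minutes <- format(round(tab$total_minutes, 4), big.mark = ",")
  tab$fte <- sprintf("%.4f", tab$fte)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export a result object to JSON or CSV
#'
#' Writes flow results, run reports, sweeps, capacity results and
#' simulation results in stable, documented layouts. JSON payloads carry
#' full-precision numbers; CSV uses 17 significant digits. Identical
#' inputs produce byte-identical payloads — no timestamps are embedded in
#' the data (provenance blocks identify the model by content hash).
#'
#' CSV layouts: a `flow_result` has rows `kind,id,label,expected_count,
#' minutes,fte` (task rows fill `expected_count`; resource rows fill
#' `minutes` and `fte`); a `sweep_result` has header
#' `param,<resource ids...>,dominant` with crossovers appended as a
#' commented `#crossovers` block; a `capacity_result` has one row per
#' resource plus `#max_population` / `#bottleneck` pragmas.
#'
#' @param x A `flow_result`, `run_report`, `sweep_result`,
#'   `capacity_result` or `simulation_result`.
#' @param path Destination file, or `NULL` to return the text.
#' @param format `"json"` or `"csv"`.
#' @return The exported text, invisibly when written to a file.
#' @export
export_result <- function(x, path = NULL, format = c("json", "csv")) {
  format <- match.arg(format)
  text <- if (format == "json") export_json(x) else export_csv(x)
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

export_json <- function(x) {
  payload <- result_payload(x)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   na = "null")
}

# Plain-list view of each result class, shared by the JSON exporter.
result_payload <- function(x) {
  if (inherits(x, "flow_result")) {
    list(type = "flow_result",
         population = x$population,
         fte_basis_minutes = x$fte_basis_minutes,
         horizon_weeks = x$horizon_weeks,
         expected_count = as.list(x$expected_count),
         total_minutes = as.list(x$total_minutes),
         fte = as.list(x$fte))
  } else if (inherits(x, "run_report")) {
    list(type = "run_report",
         summary = x$summary,
         provenance = x$provenance,
         ranking = x$ranking,
         tie = x$tie,
         per_task = x$per_task,
         flow = result_payload(x$flow))
  } else if (inherits(x, "sweep_result")) {
    list(type = "sweep_result",
         kind = x$spec$kind,
         task_id = x$spec$task_id,
         branch_next_id = x$spec$branch_next_id,
         resource_id = x$spec$resource_id,
         fte_basis_minutes = x$fte_basis_minutes,
         horizon_weeks = x$horizon_weeks,
         grid = x$grid,
         fte_curves = as.data.frame(x$fte_curves),
         dominant = as.character(x$dominant),
         crossovers = x$crossovers)
  } else if (inherits(x, "capacity_result")) {
    list(type = "capacity_result",
         max_population = x$max_population,
         bottleneck = as.character(x$bottleneck),
         bottleneck_tie = isTRUE(attr(x$bottleneck, "tie")),
         horizon_weeks = x$staffing$horizon_weeks,
         fte_basis_minutes = x$fte_basis_minutes,
         per_patient_minutes = as.list(x$per_patient_minutes),
         limit = as.list(x$limit),
         slack = as.list(x$slack),
         zero_staffed = x$zero_staffed)
  } else if (inherits(x, "simulation_result")) {
    list(type = "simulation_result",
         n_patients = x$n_patients,
         seed = x$seed,
         visits = as.list(x$visits),
         minutes = as.list(x$minutes),
         per_patient_mean = as.list(x$per_patient_mean),
         per_patient_se = as.list(x$per_patient_se))
  } else {
    stop("don't know how to export objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

export_csv <- function(x) {
  if (inherits(x, "run_report")) x <- x$flow
  if (inherits(x, "flow_result")) {
    rows <- c("kind,id,expected_count,minutes,fte",
              vapply(names(x$expected_count), function(id) {
                paste("task", csv_quote(id), num17(x$expected_count[[id]]),
                      "", "", sep = ",")
              }, character(1)),
              vapply(names(x$total_minutes), function(r) {
                paste("resource", csv_quote(r), "",
                      num17(x$total_minutes[[r]]), num17(x$fte[[r]]),
                      sep = ",")
              }, character(1)))
    return(paste(rows, collapse = "\n"))
  }
  if (inherits(x, "sweep_result")) {
    res <- colnames(x$fte_curves)
    header <- paste(c("param", res, "dominant"), collapse = ",")
    rows <- vapply(seq_along(x$grid), function(i) {
      paste(c(num17(x$grid[i]), num17(x$fte_curves[i, ]),
              csv_quote(x$dominant[i])), collapse = ",")
    }, character(1))
    block <- c(header, rows)
    if (nrow(x$crossovers)) {
      block <- c(block, "#crossovers", "param,overtaken,overtaking,fte",
                 vapply(seq_len(nrow(x$crossovers)), function(i) {
                   paste(c(num17(x$crossovers$param[i]),
                           csv_quote(x$crossovers$overtaken[i]),
                           csv_quote(x$crossovers$overtaking[i]),
                           num17(x$crossovers$fte[i])), collapse = ",")
                 }, character(1)))
    }
    return(paste(block, collapse = "\n"))
  }
  if (inherits(x, "capacity_result")) {
    rows <- c(sprintf("#max_population=%s", num17(x$max_population)),
              sprintf("#bottleneck=%s", as.character(x$bottleneck)),
              "resource,per_patient_minutes,supported_population,slack_minutes",
              vapply(names(x$per_patient_minutes), function(r) {
                paste(c(csv_quote(r), num17(x$per_patient_minutes[[r]]),
                        num17(x$limit[[r]]), num17(x$slack[[r]])),
                      collapse = ",")
              }, character(1)))
    return(paste(rows, collapse = "\n"))
  }
  if (inherits(x, "simulation_result")) {
    rows <- c(sprintf("#n_patients=%d", x$n_patients),
              sprintf("#seed=%s", format(x$seed)),
              "resource,minutes,per_patient_mean,per_patient_se",
              vapply(names(x$minutes), function(r) {
                paste(c(csv_quote(r), num17(x$minutes[[r]]),
                        num17(x$per_patient_mean[[r]]),
                        num17(x$per_patient_se[[r]])), collapse = ",")
              }, character(1)))
    return(paste(rows, collapse = "\n"))
  }
  stop("don't know how to export objects of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
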