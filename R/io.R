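#' Read a process-map model file
#'
#' Two on-disk formats are supported and auto-detected.
#'
#' **CSV dialect** (UTF-8, comma-separated, header row): a leading pragma
#' line `#population=<N>` carries the initial population, then columns
#' `task_id,label,<resource_1>,...,<resource_K>,outcomes`. Resource columns
#' hold minutes-per-patient as decimals. The `outcomes` column holds
#' semicolon-separated `next_id:percent` pairs (e.g. `2:30;3:70`), empty for
#' terminal tasks. Percentages are written as printed in program tables
#' ("30" means 30%, "0.5" means 0.5%) and stored internally as fractions.
#'
#' **JSON**: one document with `resources` (list of `{id, description}`),
#' `tasks` (list of `{id, label, minutes: {resource: min},
#' outcomes: [{next, percent}]}`), `root` and `population`.
#'
#' @param source Path to a model file, or the model text itself.
#' @param format `"csv"`, `"json"`, or `NULL` to auto-detect from the file
#'   extension (or, for literal text, from the leading character).
#' @return A [process_map()].
#' @seealso [write_model()]
#' @export
parse_model <- function(source, format = NULL) {
  stopifnot(is.character(source), length(source) == 1L)
  is_path <- !grepl("\n", source, fixed = TRUE) && file.exists(source)
  if (is_path) {
    text <- paste(readLines(source, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    if (is.null(format)) {
      ext <- tolower(tools::file_ext(source))
      format <- if (ext == "json") "json" else "csv"
    }
  } else {
    text <- source
    if (is.null(format)) {
      first <- substr(trimws(text), 1L, 1L)
      format <- if (identical(first, "{")) "json" else "csv"
    }
  }
  format <- match.arg(format, c("csv", "json"))
  switch(format,
         csv = parse_model_csv(text),
         json = parse_model_json(text))
}

parse_model_csv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  pragma <- grepl("^#", lines)
  population <- 0
  for (pl in lines[pragma]) {
    mkey <- regmatches(pl, regexec("^#\\s*population\\s*=\\s*([0-9eE.+-]+)\\s*$", pl))[[1]]
    if (length(mkey) == 2L) population <- as.numeric(mkey[2])
  }
  body <- lines[!pragma]
  if (length(body) < 2L) stop("model CSV needs a header row and at least one task",
                              call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("task_id", "label", "outcomes")
  if (!all(required %in% names(df))) {
    stop("model CSV header must contain task_id, label and outcomes columns",
         call. = FALSE)
  }
  resource_ids <- setdiff(names(df), required)
  if (anyDuplicated(df$task_id)) {
    stop("duplicate task id(s) in model file: ",
         paste(unique(df$task_id[duplicated(df$task_id)]), collapse = ", "),
         call. = FALSE)
  }
  tasks <- lapply(seq_len(nrow(df)), function(i) {
    minutes <- numeric(0)
    for (r in resource_ids) {
      cell <- trimws(df[[r]][i])
      val <- if (nzchar(cell)) suppressWarnings(as.numeric(cell)) else 0
      if (is.na(val)) {
        stop(sprintf("row %d (task %s): resource column '%s' is not numeric: '%s'",
                     i, df$task_id[i], r, cell), call. = FALSE)
      }
      if (val != 0) minutes[r] <- val
    }
    task(df$task_id[i], df$label[i], minutes = minutes,
         outcomes = parse_outcomes_cell(df$outcomes[i], i, df$task_id[i]))
  })
  process_map(resources = resource_ids, tasks = tasks,
              root = NULL, population = population)
}

# "2:30;3:70" -> two branches with probabilities .30 and .70
parse_outcomes_cell <- function(cell, row, task_id) {
  cell <- trimws(cell)
  if (!nzchar(cell) || toupper(cell) %in% c("N/A", "NA")) return(NULL)
  pairs <- strsplit(cell, ";", fixed = TRUE)[[1]]
  rows <- lapply(pairs, function(p) {
    bits <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(bits) != 2L) {
      stop(sprintf("row %d (task %s): malformed outcome '%s' (expected next_id:percent)",
                   row, task_id, p), call. = FALSE)
    }
    pct <- suppressWarnings(as.numeric(bits[2]))
    if (is.na(pct)) {
      stop(sprintf("row %d (task %s): outcome percentage is not numeric: '%s'",
                   row, task_id, bits[2]), call. = FALSE)
    }
    branch(trimws(bits[1]), pct / 100)
  })
  do.call(rbind, rows)
}

parse_model_json <- function(text) {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  resources <- do.call(rbind, lapply(doc$resources, function(r) {
    data.frame(id = as.character(r$id),
               description = if (is.null(r$description)) "" else as.character(r$description),
               stringsAsFactors = FALSE)
  }))
  tasks <- lapply(doc$tasks, function(t) {
    minutes <- unlist(t$minutes)
    if (is.null(minutes)) minutes <- numeric(0)
    outcomes <- NULL
    if (length(t$outcomes)) {
      outcomes <- do.call(rbind, lapply(t$outcomes, function(o) {
        branch(o[["next"]], as.numeric(o$percent) / 100)
      }))
    }
    task(t$id, if (is.null(t$label)) "" else t$label,
         minutes = minutes, outcomes = outcomes)
  })
  process_map(resources = resources, tasks = tasks,
              root = if (is.null(doc$root)) NULL else as.character(doc$root),
              population = if (is.null(doc$population)) 0 else as.numeric(doc$population))
}

#' Write a process-map model file
#'
#' Serialises a model to the CSV dialect or the JSON schema read by
#' [parse_model()]. Numbers are written with 17 significant digits so a
#' round-trip preserves minutes and probabilities to better than 1e-12.
#' A model with validation errors is refused.
#'
#' @param m A valid `process_map`.
#' @param path Destination file, or `NULL` to return the text.
#' @param format `"csv"`, `"json"`, or `NULL` to pick from the path
#'   extension (`csv` when there is no path).
#' @return The serialised text, invisibly when written to a file.
#' @export
write_model <- function(m, path = NULL, format = NULL) {
  stopifnot(inherits(m, "process_map"))
  stop_if_invalid(m)
  if (is.null(format)) {
    format <- if (!is.null(path) && tolower(tools::file_ext(path)) == "json")
      "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  text <- switch(format,
                 csv = write_model_csv(m),
                 json = write_model_json(m))
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

# 15 significant digits: clean output for table-like values while keeping
# round-trip error near machine precision (well under the 1e-12 contract).
num17 <- function(x) {
  trimws(formatC(x, format = "g", digits = 15))
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

write_model_csv <- function(m) {
  resource_ids <- m$resources$id
  header <- paste(c("task_id", "label", resource_ids, "outcomes"), collapse = ",")
  rows <- vapply(m$tasks, function(t) {
    mins <- resolved_minutes(t, resource_ids)
    outcomes <- if (nrow(t$outcomes) == 0L) "" else
      paste(sprintf("%s:%s", t$outcomes$next_id,
                    num17(t$outcomes$probability * 100)),
            collapse = ";")
    paste(c(csv_quote(t$id), csv_quote(t$label), num17(mins), csv_quote(outcomes)),
          collapse = ",")
  }, character(1))
  paste(c(sprintf("#population=%s", num17(m$population)), header, rows),
        collapse = "\n")
}

write_model_json <- function(m) {
  tasks <- lapply(m$tasks, function(t) {
    out <- list(id = t$id, label = t$label,
                minutes = as.list(t$minutes))
    if (nrow(t$outcomes)) {
      out$outcomes <- lapply(seq_len(nrow(t$outcomes)), function(i) {
        list(`next` = t$outcomes$next_id[i],
             percent = t$outcomes$probability[i] * 100)
      })
    } else {
      out$outcomes <- list()
    }
    out
  })
  doc <- list(
    resources = lapply(seq_len(nrow(m$resources)), function(i) {
      list(id = m$resources$id[i], description = m$resources$description[i])
    }),
    tasks = unname(tasks),
    root = m$root,
    population = m$population
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
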