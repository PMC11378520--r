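#' Describe available staffing
#'
#' @param ... Named FTE counts, e.g. `NN = 100, Radiologist = 50`, or a
#'   single named vector/list. Resources not listed are treated as
#'   unlimited, which lets planners ask single-resource questions;
#'   [max_population()] has a `strict` flag to forbid omissions.
#' @param horizon_weeks Planning horizon in 40-hour weeks (> 0).
#' @return A `staffing_scenario`: list with `available_fte` (named numeric)
#'   and `horizon_weeks`.
#' @export
staffing_scenario <- function(..., horizon_weeks = 1) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots))) {
    dots <- as.list(dots[[1]])  # a single named vector or list was passed
  }
  if (!length(dots) || is.null(names(dots)) || any(!nzchar(names(dots)))) {
    stop("staffing needs named FTE values, e.g. staffing_scenario(NN = 100)",
         call. = FALSE)
  }
  fte <- vapply(dots, as.numeric, numeric(1))
  if (any(fte < 0) || anyNA(fte)) {
    stop("available FTEs must be non-negative numbers", call. = FALSE)
  }
  if (!is.numeric(horizon_weeks) || horizon_weeks <= 0) {
    stop("`horizon_weeks` must be positive", call. = FALSE)
  }
  structure(list(available_fte = fte, horizon_weeks = horizon_weeks),
            class = "staffing_scenario")
}

#' Expected resource minutes per entering patient
#'
#' The flow totals at unit population. Because the flow is exactly linear
#' in the population, `compute_flow(m, N)$total_minutes` equals `N` times
#' this vector, which makes it the natural unit for capacity questions.
#'
#' @param m A valid `process_map`.
#' @return Named numeric vector, minutes per entering patient by resource.
#' @examples
#' per_patient_minutes(build_va_demo())
#' @export
per_patient_minutes <- function(m) {
  compute_flow(m, population = 1)$total_minutes
}

#' Invert the model: maximum screenable population under given staffing
#'
#' Each resource can supply `available_fte x fte_basis_minutes x
#' horizon_weeks` minutes over the planning horizon, and each entering
#' patient consumes [per_patient_minutes()] of it. The largest population
#' the program can fully process is therefore the minimum, over resources
#' with positive per-patient need, of available minutes divided by
#' per-patient minutes; the resource attaining that minimum is the
#' bottleneck — the one whose capacity binds first as the screened
#' population grows. Consistent with the model's 100%-utilisation
#' assumption, this is a pure min-ratio inversion with no queueing.
#'
#' @param m A valid `process_map`.
#' @param staffing A [staffing_scenario()].
#' @param fte_basis_minutes Minutes one FTE works per week (default 2400).
#' @param strict If `TRUE`, error when `staffing` omits a resource the model
#'   consumes; by default omitted resources are unlimited.
#' @return A `capacity_result`: list with `per_patient_minutes`,
#'   `max_population`, `bottleneck` (lexicographically first arg-min,
#'   attribute `tie` when several bind at once), `limit` (per-resource
#'   population each resource alone could support), `slack` (unused minutes
#'   at the maximum population; zero for the bottleneck) and
#'   `zero_staffed` (constraining resources with no staff at all, making
#'   `max_population` 0).
#' @examples
#' max_population(build_va_demo(),
#'                staffing_scenario(NN = 100, PCP = 100, Radiologist = 50))
#' @export
max_population <- function(m, staffing, fte_basis_minutes = 2400,
                           strict = FALSE) {
  stopifnot(inherits(staffing, "staffing_scenario"))
  ppm <- per_patient_minutes(m)
  unknown <- setdiff(names(staffing$available_fte), names(ppm))
  if (length(unknown)) {
    stop("staffing names unknown resource(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  needed <- names(ppm)[ppm > 0]
  omitted <- setdiff(needed, names(staffing$available_fte))
  if (strict && length(omitted)) {
    stop("strict staffing: no FTE value for resource(s): ",
         paste(omitted, collapse = ", "), call. = FALSE)
  }
  avail_fte <- stats::setNames(rep(Inf, length(ppm)), names(ppm))
  avail_fte[names(staffing$available_fte)] <- staffing$available_fte
  avail_min <- avail_fte * fte_basis_minutes * staffing$horizon_weeks

  if (!any(is.finite(avail_min[needed]))) {
    stop("no resource with positive per-patient minutes has finite staffing; ",
         "capacity is unbounded", call. = FALSE)
  }
  limit <- stats::setNames(rep(Inf, length(ppm)), names(ppm))
  limit[needed] <- avail_min[needed] / ppm[needed]
  max_pop <- min(limit)
  # ties detected to a relative 1e-9: ratios that are equal on paper can
  # differ in the last floating-point ulp
  binding <- sort(names(limit)[limit <= max_pop + 1e-9 * max(1, abs(max_pop))],
                  method = "radix")
  zero_staffed <- sort(needed[avail_min[needed] == 0], method = "radix")

  slack <- avail_min - ppm * max_pop  # Inf for unlimited resources

  structure(
    list(per_patient_minutes = ppm,
         max_population = max_pop,
         bottleneck = structure(binding[1L], tie = length(binding) > 1L),
         limit = limit,
         slack = slack,
         zero_staffed = zero_staffed,
         staffing = staffing,
         fte_basis_minutes = fte_basis_minutes),
    class = "capacity_result"
  )
}

#' The resource whose capacity binds first
#'
#' Convenience wrapper around [max_population()] returning only the
#' bottleneck resource id (lexicographically first on exact ties, with
#' attribute `tie = TRUE`).
#'
#' @inheritParams max_population
#' @return A resource id.
#' @export
bottleneck <- function(m, staffing, fte_basis_minutes = 2400,
                       strict = FALSE) {
  max_population(m, staffing, fte_basis_minutes = fte_basis_minutes,
                 strict = strict)$bottleneck
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("<capacity_result>\n")
  cat("  max population:", format(round(x$max_population, 4), big.mark = ","),
      "\n")
  cat("  bottleneck:    ", x$bottleneck,
      if (isTRUE(attr(x$bottleneck, "tie"))) " (tie)" else "", "\n", sep = "")
  tab <- data.frame(resource = names(x$per_patient_minutes),
                    min_per_patient = round(x$per_patient_minutes, 5),
                    supported_pop = round(x$limit, 1),
                    slack_minutes = round(x$slack, 4))
  print(tab, row.names = FALSE)
  if (length(x$zero_staffed)) {
    cat("  zero-staffed constraining resource(s): ",
        paste(x$zero_staffed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
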