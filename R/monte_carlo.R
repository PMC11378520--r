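#' Simulate a patient cohort through the process map
#'
#' Patient-level stochastic counterpart of [compute_flow()], used as an
#' independent verification of the analytic expectations. Each of
#' `n_patients` patients starts at the root and, at every task visited,
#' samples one outgoing branch from the task's categorical outcome
#' distribution until a terminal task is reached. Sampling uses
#' cumulative-probability inversion with branches in file order; a uniform
#' draw landing exactly on a cumulative boundary resolves toward the
#' earlier branch, which keeps results platform-stable.
#'
#' Patients at the same task are advanced together (one uniform draw per
#' patient per visited task, tasks processed in topological order), so the
#' run is fully reproducible given `(model, n_patients, seed)`. The
#' caller's RNG state is left untouched.
#'
#' @param m A valid `process_map`.
#' @param n_patients Number of simulated patients (>= 0).
#' @param seed Integer seed; mandatory, no implicit randomness.
#' @return A `simulation_result`: list with `n_patients`, `seed`, `visits`
#'   (named integer, patients visiting each task), `minutes` (named numeric,
#'   total simulated minutes per resource), `per_patient_mean` and
#'   `per_patient_se` (mean and standard error of per-patient resource
#'   minutes).
#' @examples
#' sim <- simulate_cohort(build_va_demo(), n_patients = 1000, seed = 42)
#' sim$per_patient_mean
#' @export
simulate_cohort <- function(m, n_patients, seed) {
  stop_if_invalid(m)
  stopifnot(is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 0)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulations must be reproducible", call. = FALSE)
  }
  n <- as.integer(n_patients)
  resource_ids <- m$resources$id
  topo <- topological_order(m)

  visits <- stats::setNames(integer(length(topo)), topo)
  patient_minutes <- matrix(0, nrow = n, ncol = length(resource_ids),
                            dimnames = list(NULL, resource_ids))
  # patients currently sitting at each task
  at <- stats::setNames(vector("list", length(topo)), topo)
  at[[m$root]] <- seq_len(n)

  with_seed(seed, {
    for (id in topo) {
      idx <- at[[id]]
      if (!length(idx)) next
      t <- m$tasks[[id]]
      visits[id] <- length(idx)
      if (length(t$minutes)) {
        patient_minutes[idx, names(t$minutes)] <-
          patient_minutes[idx, names(t$minutes), drop = FALSE] +
          rep(t$minutes, each = length(idx))
      }
      if (nrow(t$outcomes)) {
        cum <- cumsum(t$outcomes$probability)
        cum[length(cum)] <- 1  # guard against cumulative rounding shortfall
        u <- stats::runif(length(idx))
        # branch j chosen iff cum_{j-1} < u <= cum_j (ties to earlier branch)
        chosen <- findInterval(u, cum, left.open = TRUE) + 1L
        for (k in seq_len(nrow(t$outcomes))) {
          sel <- idx[chosen == k]
          if (length(sel)) {
            nxt <- t$outcomes$next_id[k]
            at[[nxt]] <- c(at[[nxt]], sel)
          }
        }
      }
      at[[id]] <- integer(0)
    }
  })

  total <- colSums(patient_minutes)
  mean_pp <- if (n > 0) total / n else stats::setNames(
    rep(NA_real_, length(resource_ids)), resource_ids)
  se_pp <- if (n > 1) apply(patient_minutes, 2, stats::sd) / sqrt(n) else
    stats::setNames(rep(NA_real_, length(resource_ids)), resource_ids)

  structure(
    list(n_patients = n, seed = seed,
         visits = visits[order_task_ids(names(visits))],
         minutes = total,
         per_patient_mean = mean_pp,
         per_patient_se = se_pp),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> ", format(x$n_patients, big.mark = ","),
      " patients, seed ", x$seed, "\n", sep = "")
  tab <- data.frame(resource = names(x$minutes),
                    minutes = round(x$minutes, 2),
                    per_patient = round(x$per_patient_mean, 5),
                    se = signif(x$per_patient_se, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare a simulated cohort with the analytic flow
#'
#' For each resource, computes the standardised discrepancy
#' `z = (simulated minutes - analytic minutes) / (n * per_patient_se)`
#' (the denominator is the standard error of the simulated total) and flags
#' `|z| > 4`. A resource whose per-patient minutes have zero sampling
#' variance (e.g. a single-path model) has no defined z; it is reported as
#' `"exact"` when simulated and analytic totals agree to within 1e-9
#' relative, and flagged otherwise.
#'
#' @param sim A `simulation_result`.
#' @param flow A `flow_result` from the same model, computed at
#'   `population = sim$n_patients`.
#' @return A data frame with one row per resource: `resource`, `simulated`,
#'   `analytic`, `z`, `status` (`"ok"`, `"exact"` or `"flagged"`) and
#'   `flagged`.
#' @export
compare_to_analytic <- function(sim, flow) {
  stopifnot(inherits(sim, "simulation_result"), inherits(flow, "flow_result"))
  if (!setequal(names(sim$minutes), names(flow$total_minutes))) {
    stop("resource sets of simulation and flow do not match", call. = FALSE)
  }
  res <- names(sim$minutes)
  analytic <- flow$total_minutes[res]
  simulated <- sim$minutes[res]
  se_total <- sim$n_patients * sim$per_patient_se[res]
  z <- rep(NA_real_, length(res))
  status <- character(length(res))
  for (i in seq_along(res)) {
    if (is.na(se_total[i]) || se_total[i] == 0) {
      agree <- abs(simulated[i] - analytic[i]) <=
        1e-9 * max(1, abs(analytic[i]))
      status[i] <- if (agree) "exact" else "flagged"
    } else {
      z[i] <- (simulated[i] - analytic[i]) / se_total[i]
      status[i] <- if (abs(z[i]) > 4) "flagged" else "ok"
    }
  }
  data.frame(resource = res, simulated = unname(simulated),
             analytic = unname(analytic), z = z, status = status,
             flagged = status == "flagged",
             stringsAsFactors = FALSE, row.names = NULL)
}
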