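#' The demonstrative VA lung-cancer-screening model
#'
#' The packaged reference model of a Veterans Affairs lung cancer screening
#' program (hybrid model: the primary care provider is the gatekeeper).
#' 75,000 at-risk Veterans enter at task 1; a computer eligibility check
#' splits them 30% eligible / 70% ineligible; eligible patients flow through
#' shared decision making, LDCT scheduling, nurse-navigator follow-up and
#' the scan itself, whose result is routed by LungRADS score; everyone ends
#' at task 13, completion of one screening cycle. Three human resources are
#' modelled: nurse navigators (NN), primary care providers (PCP) and
#' radiologists.
#'
#' Per-task minutes: task 2 PCP 3; task 3 NN 1; task 4 PCP 1; task 5 PCP 2;
#' task 6 NN 5; tasks 7-8 Radiologist 10; tasks 9-12 NN 10; tasks 1 and 13
#' consume no resource time.
#'
#' @return A valid `process_map` with 13 tasks, 3 resources, root task 1,
#'   terminal task 13 and initial population 75,000.
#' @examples
#' m <- build_va_demo()
#' compute_flow(m)
#' @export
build_va_demo <- function() {
  resources <- data.frame(
    id = c("NN", "PCP", "Radiologist"),
    description = c("Nurse navigator: tracks screened patients and follows up results",
                    "Primary care provider: gatekeeper for screening",
                    "Radiologist: reads low-dose CT scans"),
    stringsAsFactors = FALSE
  )
  tasks <- list(
    task(1, "Computer checks eligibility of VA population",
         outcomes = list(branch(2, 0.30), branch(3, 0.70))),
    task(2, "PCP discusses screening and offers smoking cessation",
         minutes = c(PCP = 3),
         outcomes = list(branch(3, 0.40), branch(5, 0.60))),
    task(3, "NN offers smoking cessation",
         minutes = c(NN = 1),
         outcomes = list(branch(4, 0.60), branch(13, 0.40))),
    task(4, "PCP connects to smoking cessation program",
         minutes = c(PCP = 1),
         outcomes = list(branch(13, 1))),
    task(5, "PCP schedules LDCT",
         minutes = c(PCP = 2),
         outcomes = list(branch(6, 0.10), branch(7, 0.90))),
    task(6, "NN follows up",
         minutes = c(NN = 5),
         outcomes = list(branch(7, 0.75), branch(13, 0.25))),
    task(7, "Radiologist conducts LDCT",
         minutes = c(Radiologist = 10),
         outcomes = list(branch(8, 0.005), branch(9, 0.496),
                         branch(10, 0.418), branch(11, 0.034),
                         branch(12, 0.047))),
    task(8, "LungRADS 0: radiologist conducts additional LDCT",
         minutes = c(Radiologist = 10),
         outcomes = list(branch(13, 1))),
    task(9, "LungRADS 1a/2a/2b: PCP and NN follow up to continue annual LDCT",
         minutes = c(NN = 10),
         outcomes = list(branch(13, 1))),
    task(10, "LungRADS 3a: NN follows up",
         minutes = c(NN = 10),
         outcomes = list(branch(13, 1))),
    task(11, "LungRADS 4a/4b/4x: NN follows up",
         minutes = c(NN = 10),
         outcomes = list(branch(13, 1))),
    task(12, "LungRADS S: NN notifies PCP for follow up",
         minutes = c(NN = 10),
         outcomes = list(branch(13, 1))),
    task(13, "Patients complete one cycle of screening in the program")
  )
  process_map(resources = resources, tasks = tasks, root = "1",
              population = 75000)
}

#' Generate a random valid process map
#'
#' Draws a random layered DAG for property-style testing. Tasks are placed
#' in a topological sequence and edges only point forward, so the result is
#' acyclic by construction; branch probabilities are drawn uniformly and
#' normalised to sum to one; minutes are uniform on [0, 15]. Every task is
#' kept reachable by wiring each non-root task to at least one predecessor.
#' The generated model always passes [validate_model()] with zero errors.
#'
#' @param seed Integer seed; the same seed always yields the same model.
#' @param n_tasks Number of tasks (>= 2). The last task in the sequence is
#'   terminal; earlier tasks may also become terminal-free sinks are avoided
#'   by routing dangling branches to later tasks.
#' @param n_resources Number of resources (`R1`, `R2`, ...).
#' @param max_branching Maximum number of outcome edges per task (>= 1).
#' @param population Initial population of the generated model.
#' @return A valid `process_map`.
#' @export
random_model <- function(seed, n_tasks = 10, n_resources = 3,
                         max_branching = 3, population = 1000) {
  if (n_tasks < 2L) stop("`n_tasks` must be at least 2", call. = FALSE)
  if (max_branching < 1L) stop("`max_branching` must be at least 1", call. = FALSE)
  if (n_resources < 1L) stop("`n_resources` must be at least 1", call. = FALSE)
  with_seed(seed, {
    ids <- as.character(seq_len(n_tasks))
    resources <- paste0("R", seq_len(n_resources))
    tasks <- vector("list", n_tasks)
    # Guarantee reachability: every task i > 1 gets one incoming edge from a
    # uniformly chosen predecessor; extra forward edges are then added up to
    # max_branching.
    incoming_from <- c(NA_integer_,
                       vapply(seq_len(n_tasks)[-1], function(i) {
                         sample.int(i - 1L, 1L)
                       }, integer(1)))
    targets <- vector("list", n_tasks)
    for (i in seq_len(n_tasks - 1L)) {
      forced <- which(incoming_from == i)
      pool <- setdiff(seq(i + 1L, n_tasks), forced)
      n_extra <- sample.int(max_branching, 1L) - length(forced)
      extra <- if (n_extra > 0L && length(pool))
        pool[sample.int(length(pool), min(n_extra, length(pool)))] else integer(0)
      targets[[i]] <- sort(unique(c(forced, extra)))
    }
    for (i in seq_len(n_tasks)) {
      mins <- round(stats::runif(n_resources, 0, 15), 3)
      mins <- stats::setNames(mins, resources)
      mins <- mins[mins > 0]
      tgt <- targets[[i]]
      outcomes <- NULL
      if (length(tgt)) {
        w <- stats::runif(length(tgt), 0.05, 1)
        p <- w / sum(w)
        outcomes <- do.call(rbind, Map(branch, as.character(tgt), p))
      }
      tasks[[i]] <- task(ids[i], paste("step", ids[i]),
                         minutes = mins, outcomes = outcomes)
    }
    process_map(resources = resources, tasks = tasks, root = "1",
                population = population)
  })
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}
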