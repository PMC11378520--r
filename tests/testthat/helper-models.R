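# Small models built in code for the tests.

# Deterministic chain 1 -> 2 -> ... -> n, every branch probability 1.
chain_model <- function(n = 3, minutes_per_task = c(A = 2), population = 10) {
  tasks <- lapply(seq_len(n), function(i) {
    task(i, paste("step", i), minutes = minutes_per_task,
         outcomes = if (i < n) list(branch(i + 1, 1)) else NULL)
  })
  process_map(resources = names(minutes_per_task), tasks = tasks,
              root = "1", population = population)
}

# Root splitting to two terminal leaves with probability p / 1 - p.
fork_model <- function(p = 0.3, population = 100) {
  process_map(
    resources = c("A", "B"),
    tasks = list(
      task(1, "gate", outcomes = list(branch(2, p), branch(3, 1 - p))),
      task(2, "left", minutes = c(A = 4)),
      task(3, "right", minutes = c(B = 6))
    ),
    population = population
  )
}

# Replace one task of a model (used to inject defects).
swap_task <- function(m, t) {
  m$tasks[[t$id]] <- t
  m
}

expect_codes <- function(report, codes) {
  expect_setequal(unique(report$errors$code), codes)
}
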