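test_that("topological order respects every edge and breaks ties by id", {
  m <- build_va_demo()
  topo <- topological_order(m)
  pos <- stats::setNames(seq_along(topo), topo)
  expect_lt(pos[["1"]], pos[["2"]])
  expect_lt(pos[["2"]], pos[["5"]])
  for (t in m$tasks) {
    for (nxt in t$outcomes$next_id) {
      expect_lt(pos[[t$id]], pos[[nxt]])
    }
  }
  # single-task model
  expect_identical(topological_order(chain_model(1)), "1")
  # random models: verify edge-by-edge
  for (seed in c(3, 17)) {
    rm <- random_model(seed, n_tasks = 25, max_branching = 4)
    topo_r <- topological_order(rm)
    pos_r <- stats::setNames(seq_along(topo_r), topo_r)
    for (t in rm$tasks) {
      for (nxt in t$outcomes$next_id) {
        expect_lt(pos_r[[t$id]], pos_r[[nxt]])
      }
    }
  }
})

test_that("topological order matches an independent graph library", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 9, 31)) {
    m <- random_model(seed, n_tasks = 20, max_branching = 3)
    edges <- do.call(rbind, lapply(m$tasks, function(t) {
      if (nrow(t$outcomes)) cbind(t$id, t$outcomes$next_id)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    expect_true(igraph::is_dag(g))
    ours <- topological_order(m)
    pos <- stats::setNames(seq_along(ours), ours)
    ig_order <- igraph::V(g)$name[as.integer(igraph::topo_sort(g))]
    # both are valid linear extensions of the same partial order
    for (i in seq_len(nrow(edges))) {
      expect_lt(pos[[edges[i, 1]]], pos[[edges[i, 2]]])
    }
    expect_setequal(ours, ig_order)
  }
})

test_that("expected flow through the demo model matches hand propagation", {
  fl <- compute_flow(build_va_demo())
  expect_equal(fl$expected_count[["1"]], 75000)
  expect_equal(fl$expected_count[["2"]], 22500, tolerance = 1e-12)
  expect_equal(fl$expected_count[["3"]], 61500, tolerance = 1e-12)
  expect_equal(fl$expected_count[["7"]], 13162.5, tolerance = 1e-12)
  expect_equal(fl$expected_count[["13"]], 75000, tolerance = 1e-12)

  expect_equal(fl$total_minutes[["PCP"]], 131400, tolerance = 1e-12)
  expect_equal(fl$total_minutes[["Radiologist"]], 132283.125, tolerance = 1e-12)
  expect_equal(fl$total_minutes[["NN"]], 199216.875, tolerance = 1e-12)

  expect_equal(fl$fte[["PCP"]], 54.75, tolerance = 1e-12)
  expect_equal(fl$fte[["Radiologist"]], 132283.125 / 2400, tolerance = 1e-12)
  expect_equal(fl$fte[["NN"]], 199216.875 / 2400, tolerance = 1e-12)
})

test_that("patients are conserved at the terminal steps", {
  m <- build_va_demo()
  fl <- compute_flow(m)
  expect_equal(sum(fl$expected_count[terminal_tasks(m)]), fl$population,
               tolerance = 1e-9)
  for (seed in 1:25) {
    rm <- random_model(seed, n_tasks = 15, max_branching = 4,
                       population = 3000)
    fr <- compute_flow(rm)
    expect_equal(sum(fr$expected_count[terminal_tasks(rm)]), 3000,
                 tolerance = 1e-9 * 3000, info = paste("seed", seed))
  }
})

test_that("zero population zeroes every output", {
  fl <- compute_flow(build_va_demo(), population = 0)
  expect_true(all(fl$expected_count == 0))
  expect_true(all(fl$total_minutes == 0))
  expect_true(all(fl$fte == 0))
})

test_that("flow scales exactly linearly with population", {
  m <- build_va_demo()
  base <- compute_flow(m, 75000)
  for (k in c(0.5, 2, 4)) {
    scaled <- compute_flow(m, 75000 * k)
    expect_identical(scaled$expected_count, base$expected_count * k)
    expect_identical(scaled$total_minutes, base$total_minutes * k)
    expect_identical(scaled$fte, base$fte * k)
  }
})

test_that("total minutes are affine in a single task duration with slope equal to its expected count", {
  m <- build_va_demo()
  base <- compute_flow(m)
  for (probe in list(c(id = "6", r = "NN"), c(id = "7", r = "Radiologist"),
                     c(id = "2", r = "PCP"))) {
    delta <- 2.5
    m2 <- m
    mins <- m2$tasks[[probe[["id"]]]]$minutes
    mins[probe[["r"]]] <- (if (probe[["r"]] %in% names(mins))
      mins[[probe[["r"]]]] else 0) + delta
    m2$tasks[[probe[["id"]]]]$minutes <- mins
    bumped <- compute_flow(m2)
    expect_equal(bumped$total_minutes[[probe[["r"]]]] -
                   base$total_minutes[[probe[["r"]]]],
                 delta * base$expected_count[[probe[["id"]]]],
                 tolerance = 1e-9)
    others <- setdiff(names(base$total_minutes), probe[["r"]])
    expect_identical(bumped$total_minutes[others], base$total_minutes[others])
  }
})

test_that("FTE conversion is plain division by the basis", {
  expect_identical(minutes_to_fte(2400, 2400), 1)
  expect_identical(minutes_to_fte(0, 2400), 0)
  expect_equal(minutes_to_fte(131400, 2400), 54.75)
  expect_error(minutes_to_fte(10, 0), "positive")
  expect_error(compute_flow(build_va_demo(), fte_basis_minutes = -1),
               "positive")
})

test_that("negative population is rejected", {
  expect_error(compute_flow(build_va_demo(), population = -5), "non-negative")
})

test_that("the demo model has exactly 15 root-to-terminal paths", {
  pt <- enumerate_paths(build_va_demo())
  expect_length(pt$paths, 15)
  expect_equal(sum(pt$probability), 1, tolerance = 1e-9)
  term <- terminal_tasks(build_va_demo())
  for (p in pt$paths) {
    expect_true(p[length(p)] %in% term)
  }
})

test_that("path enumeration reproduces the propagated totals", {
  m <- build_va_demo()
  fl <- compute_flow(m)
  pt <- enumerate_paths(m)
  expect_equal(pt$total_minutes, fl$total_minutes,
               tolerance = 1e-9)
  for (seed in 1:100) {
    rm <- random_model(seed, n_tasks = 12, max_branching = 3,
                       population = 500)
    fr <- compute_flow(rm)
    pr <- enumerate_paths(rm)
    expect_equal(sum(pr$probability), 1, tolerance = 1e-9,
                 info = paste("seed", seed))
    expect_equal(pr$total_minutes, fr$total_minutes,
                 tolerance = 1e-9 * max(1, max(fr$total_minutes)),
                 info = paste("seed", seed))
  }
})

test_that("path enumeration refuses explosive graphs", {
  # 2 parallel branches per layer, 14 layers: 2^14 paths > 10,000
  n_layers <- 14
  tasks <- list()
  for (i in seq_len(n_layers)) {
    gate <- 3 * i - 2; left <- 3 * i - 1; right <- 3 * i
    tasks <- c(tasks, list(
      task(gate, outcomes = list(branch(left, 0.5), branch(right, 0.5))),
      task(left, outcomes = list(branch(3 * i + 1, 1))),
      task(right, outcomes = list(branch(3 * i + 1, 1)))
    ))
  }
  tasks <- c(tasks, list(task(3 * n_layers + 1)))
  m <- process_map(resources = "A", tasks = tasks, root = "1",
                   population = 1)
  expect_error(enumerate_paths(m), "exceeded")
})

test_that("increasing a duration or the population never lowers any FTE", {
  m <- build_va_demo()
  base <- compute_flow(m)$fte
  up_pop <- compute_flow(m, 80000)$fte
  expect_true(all(up_pop >= base))
  m$tasks[["6"]]$minutes["NN"] <- 7
  up_dur <- compute_flow(m)$fte
  expect_true(all(up_dur >= base))
})
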