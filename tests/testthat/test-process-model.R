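test_that("the packaged VA demo model has the printed structure", {
  m <- build_va_demo()
  expect_s3_class(m, "process_map")
  expect_length(m$tasks, 13)
  expect_setequal(m$resources$id, c("NN", "PCP", "Radiologist"))
  expect_identical(m$root, "1")
  expect_identical(terminal_tasks(m), "13")
  expect_equal(m$population, 75000)

  report <- validate_model(m)
  expect_equal(nrow(report$errors), 0)
  expect_equal(nrow(report$warnings), 0)

  # LungRADS split at the scan task sums to exactly 1
  expect_identical(sum(m$tasks[["7"]]$outcomes$probability), 1)
  # every non-terminal task's outcomes sum to 1 within tolerance
  for (t in m$tasks) {
    if (nrow(t$outcomes)) {
      expect_lt(abs(sum(t$outcomes$probability) - 1), 1e-6)
    }
  }
  # canonical per-task minutes
  expect_equal(m$tasks[["2"]]$minutes, c(PCP = 3))
  expect_equal(m$tasks[["3"]]$minutes, c(NN = 1))
  expect_equal(m$tasks[["4"]]$minutes, c(PCP = 1))
  expect_equal(m$tasks[["5"]]$minutes, c(PCP = 2))
  expect_equal(m$tasks[["6"]]$minutes, c(NN = 5))
  for (id in c("7", "8")) {
    expect_equal(m$tasks[[id]]$minutes, c(Radiologist = 10))
  }
  for (id in as.character(9:12)) {
    expect_equal(m$tasks[[id]]$minutes, c(NN = 10))
  }
  expect_length(m$tasks[["1"]]$minutes, 0)
  expect_length(m$tasks[["13"]]$minutes, 0)
})

test_that("the packaged model files parse to the built fixture", {
  m <- build_va_demo()
  for (f in c("va_lcs_demo.csv", "va_lcs_demo.json")) {
    path <- system.file("extdata", f, package = "screenflow")
    parsed <- parse_model(path)
    expect_length(parsed$tasks, 13)
    expect_equal(nrow(parsed$resources), 3)
    expect_identical(parsed$root, "1")
    expect_equal(parsed$population, 75000)
    expect_true(model_equal(m, parsed))
  }
})

test_that("outcome cells parse percentages into fractions", {
  text <- paste("#population=50",
                "task_id,label,R1,outcomes",
                "1,start,0,2:30;3:70",
                "2,left,1,",
                "3,right,2,", sep = "\n")
  m <- parse_model(text)
  expect_equal(m$population, 50)
  expect_equal(m$tasks[["1"]]$outcomes$probability, c(0.30, 0.70))
  expect_identical(m$tasks[["1"]]$outcomes$next_id, c("2", "3"))
})

test_that("a one-task file yields a root that is also terminal", {
  m <- parse_model("task_id,label,R1,outcomes\n1,only,5,")
  expect_identical(m$root, "1")
  expect_identical(terminal_tasks(m), "1")
  expect_true(is_valid(m))
})

test_that("malformed files fail with located messages", {
  expect_error(parse_model("task_id,label,R1,outcomes\n1,a,0,2:30;3\n2,b,0,\n3,c,0,"),
               "malformed outcome")
  expect_error(parse_model("task_id,label,R1,outcomes\n1,a,x,\n"),
               "not numeric")
  expect_error(parse_model("task_id,label,R1,outcomes\n1,a,0,2:100\n1,b,0,\n2,c,0,"),
               "duplicate task id")
  expect_error(parse_model("task_id,R1\n1,0"), "header")
})

test_that("serialisation round-trips models to high precision", {
  m <- build_va_demo()
  expect_true(model_equal(m, parse_model(write_model(m, format = "csv"))))
  expect_true(model_equal(m, parse_model(write_model(m, format = "json"),
                                         format = "json")))

  # thirds survive the percent encoding to well under 1e-12
  m$tasks[["1"]]$outcomes$probability <- c(1 / 3, 2 / 3)
  back <- parse_model(write_model(m))
  expect_true(model_equal(m, back, tol = 1e-12))

  # random models, both dialects
  for (seed in c(7, 21, 99)) {
    rm <- random_model(seed, n_tasks = 15, n_resources = 4, max_branching = 3)
    expect_true(model_equal(rm, parse_model(write_model(rm, format = "csv"))),
                info = paste("csv seed", seed))
    expect_true(model_equal(rm, parse_model(write_model(rm, format = "json"),
                                            format = "json")),
                info = paste("json seed", seed))
  }
})

test_that("write_model refuses invalid models", {
  m <- fork_model()
  m$tasks[["1"]]$outcomes$probability <- c(0.3, 0.6)
  expect_error(write_model(m), "BAD_PROB_SUM")
})

test_that("validation reports every structural violation with its code", {
  m <- fork_model(0.3)

  bad_sum <- swap_task(m, task(1, "gate",
                               outcomes = list(branch(2, 0.30), branch(3, 0.60))))
  expect_codes(validate_model(bad_sum), "BAD_PROB_SUM")

  cyc <- swap_task(m, task(2, "left", minutes = c(A = 4),
                           outcomes = list(branch(1, 1))))
  rep_cyc <- validate_model(cyc)
  expect_true("CYCLE" %in% rep_cyc$errors$code)

  ghost <- swap_task(m, task(1, "gate",
                             outcomes = list(branch(2, 0.3), branch(99, 0.7))))
  expect_true("UNKNOWN_NEXT_ID" %in% validate_model(ghost)$errors$code)

  neg <- swap_task(m, task(2, "left", minutes = c(A = -1)))
  expect_codes(validate_model(neg), "NEGATIVE_MINUTES")

  undeclared <- swap_task(m, task(2, "left", minutes = c(Z = 1)))
  expect_codes(validate_model(undeclared), "UNKNOWN_RESOURCE")

  out_of_range <- swap_task(m, task(1, "gate",
                                    outcomes = list(branch(2, 1.4),
                                                    branch(3, -0.4))))
  expect_true("PROB_RANGE" %in% validate_model(out_of_range)$errors$code)

  # two entry points
  two_roots <- process_map(
    resources = "A",
    tasks = list(task(1, outcomes = list(branch(3, 1))),
                 task(2, outcomes = list(branch(3, 1))),
                 task(3, minutes = c(A = 1))),
    root = "1")
  expect_true("MULTIPLE_ROOTS" %in% validate_model(two_roots)$errors$code)

  # no terminal: both tasks point at each other
  loop <- process_map(
    resources = "A",
    tasks = list(task(1, outcomes = list(branch(2, 1))),
                 task(2, outcomes = list(branch(1, 1)))),
    root = "1")
  rep_loop <- validate_model(loop)
  expect_true(all(c("NO_TERMINAL", "CYCLE") %in% rep_loop$errors$code))

  # all violations are collected, not only the first
  multi <- swap_task(bad_sum, task(2, "left", minutes = c(A = -3)))
  expect_setequal(validate_model(multi)$errors$code,
                  c("BAD_PROB_SUM", "NEGATIVE_MINUTES"))
})

test_that("cycles appended to the demo model are caught", {
  m <- build_va_demo()
  m <- swap_task(m, task(13, "loop back",
                         outcomes = list(branch(1, 1))))
  report <- validate_model(m)
  expect_true("CYCLE" %in% report$errors$code)
  expect_false(is_valid(report))
  expect_error(compute_flow(m), "CYCLE")
})

test_that("unreachable tasks are reported as warnings", {
  # a floating island necessarily also introduces a second entry point (or a
  # cycle), so the warning accompanies the corresponding structural error
  m <- process_map(
    resources = "A",
    tasks = list(task(1, outcomes = list(branch(2, 1))),
                 task(2, minutes = c(A = 1)),
                 task(3, minutes = c(A = 5))),  # floating, no path from root
    root = "1")
  report <- validate_model(m)
  expect_true("UNREACHABLE_TASK" %in% report$warnings$code)
  expect_match(report$warnings$message[report$warnings$code == "UNREACHABLE_TASK"],
               "3")
  expect_codes(report, "MULTIPLE_ROOTS")
})

test_that("random models are deterministic per seed and always valid", {
  expect_true(model_equal(random_model(42), random_model(42), tol = 0))
  m1 <- random_model(1, n_tasks = 50, max_branching = 4)
  expect_length(m1$tasks, 50)
  expect_equal(nrow(validate_model(m1)$errors), 0)
  for (seed in 1:100) {
    rep <- validate_model(random_model(seed, n_tasks = 12, n_resources = 2,
                                       max_branching = 4))
    expect_equal(nrow(rep$errors), 0, info = paste("seed", seed))
  }
})

test_that("the smallest random model is a root with one certain branch", {
  m <- random_model(seed = 5, n_tasks = 2)
  expect_identical(m$root, "1")
  expect_identical(terminal_tasks(m), "2")
  expect_equal(m$tasks[["1"]]$outcomes$probability, 1)
  expect_identical(m$tasks[["1"]]$outcomes$next_id, "2")
})

test_that("generator rejects degenerate sizes", {
  expect_error(random_model(1, n_tasks = 1), "at least 2")
  expect_error(random_model(1, max_branching = 0), "at least 1")
})
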