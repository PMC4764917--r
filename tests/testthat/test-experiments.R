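test_that("run configurations round-trip through YAML", {
  cfg <- list(experiment = "fixture", fixture = "bistable-scalar",
              basis = "legendre", n = 4, alpha = 1.5, T = 100, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  expect_identical(read_run_config(path), cfg)
})

test_that("the fixture experiment writes conserved results and a manifest", {
  out <- withr::local_tempdir()
  cfg <- list(experiment = "fixture", fixture = "bistable-scalar",
              basis = "legendre", n = 4, alpha = 1.5, T = 150, seed = 5,
              t_end = 150, settle = 100)
  res <- run_experiment(cfg, out_dir = out)
  expect_true(file.exists(res$paths[["results"]]))
  tab <- utils::read.csv(res$paths[["results"]])
  expect_setequal(tab$attractor, c("plus", "minus"))
  expect_equal(sum(tab$M) + res$result$unclassified, 150L)
  man <- jsonlite::read_json(res$paths[["manifest"]])
  expect_identical(man$config$seed, 5L)
  expect_identical(man$experiment, "fixture")
  expect_match(man$schema, "run-manifest")
})

test_that("identical configurations produce byte-identical result files", {
  cfg <- list(experiment = "fixture", fixture = "bistable-scalar",
              basis = "trigonometric", n = 3, alpha = 1, T = 80, seed = 17,
              t_end = 150, settle = 100)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_experiment(cfg, out_dir = d1)
  r2 <- run_experiment(cfg, out_dir = d2)
  expect_identical(readLines(r1$paths[["results"]]),
                   readLines(r2$paths[["results"]]))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(run_experiment(list(experiment = "nope")), "experiment")
  expect_error(run_experiment(list(experiment = "hopfield-bs")), "seed")
  expect_error(fixture_system("unknown-fixture"))
})

test_that("the hopfield-bs experiment reproduces the four-basin estimate", {
  res <- run_experiment(list(experiment = "hopfield-bs", tau = 2,
                             basis = "legendre", n = 10, alpha = 6,
                             T = 300, seed = 23))
  tab <- res$table
  expect_setequal(tab$attractor, c("E1", "E2", "E3", "E4"))
  expect_true(all(tab$p_hat > 0))
  expect_equal(sum(tab$p_hat), 1)
})
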