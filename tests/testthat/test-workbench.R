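minimal_yaml <- function(extra = "") {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "connectome:",
    "  synthetic:",
    "    n_areas: 12",
    "    seed: 3",
    "numerics:",
    "  duration: 4",
    "  seed: 5",
    extra), path)
  path
}

test_that("configs load with defaults filled and reject unknown keys", {
  cfg <- load_config(minimal_yaml())
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$gradient$J_min, 0.21)
  expect_equal(cfg$mode, "distributed")
  expect_equal(cfg$connectome$synthetic$n_areas, 12)
  expect_equal(cfg$numerics$dt, 5e-4)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("nonsense: 1", "numerics: {seed: 1}"), bad)
  expect_error(load_config(bad), "nonsense")
  expect_error(load_config(tempfile(fileext = ".yaml")), "not found")
})

test_that("unresolvable area names in the protocol are reported", {
  cfg <- load_config(minimal_yaml(c("protocol:",
                                    "  type: simulate",
                                    "  events:",
                                    "  - area: V99")))
  expect_error(run_experiment(cfg, tempfile()), "V99")
})

test_that("config round trip through yaml is semantically stable", {
  cfg <- load_config(minimal_yaml())
  back <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), back)
  cfg2 <- load_config(back)
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- lapply(x, drop_nulls)
    x[!vapply(x, is.null, TRUE)]
  }
  expect_equal(drop_nulls(unclass(cfg2)), drop_nulls(unclass(cfg)))
})

test_that("a simulate experiment writes traces, summary and manifest", {
  cfg <- load_config(minimal_yaml(c("protocol:",
                                    "  type: simulate",
                                    "  events:",
                                    "  - area: A1")))
  out1 <- tempfile()
  res <- run_experiment(cfg, out1)
  expect_true(file.exists(file.path(out1, "traces.csv")))
  expect_true(file.exists(file.path(out1, "delay_summary.json")))
  man <- jsonlite::fromJSON(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 5)
  expect_equal(man$config$numerics$duration, 4)
  tr <- utils::read.csv(file.path(out1, "traces.csv"))
  expect_setequal(names(tr), c("time", "area", "population", "rate"))
  expect_setequal(unique(tr$population), c("A", "B", "C"))
  # identical configs give byte-identical outputs
  out2 <- tempfile()
  run_experiment(cfg, out2)
  expect_identical(readLines(file.path(out1, "traces.csv")),
                   readLines(file.path(out2, "traces.csv")))
})

test_that("census and silence experiments form a pipeline", {
  cfg <- load_config(minimal_yaml(c("G: 0.3",
                                    "gradient: {J_max: 0.5}",
                                    "mode: custom",
                                    "protocol:",
                                    "  type: census",
                                    "  n_samples: 25",
                                    "  relax_time: 10")))
  out <- tempfile()
  cen <- run_experiment(cfg, out)
  expect_true(file.exists(file.path(out, "census.json")))
  expect_true(file.exists(file.path(out, "census_summary.csv")))
  cfg2 <- load_config(minimal_yaml(c("G: 0.3",
                                     "gradient: {J_max: 0.5}",
                                     "mode: custom",
                                     "protocol:",
                                     "  type: silence",
                                     sprintf("  census_file: %s",
                                             file.path(out, "census.json")),
                                     "  silenced_sets:",
                                     "  - [A12]",
                                     "  - [A1]")))
  out2 <- tempfile()
  surv <- run_experiment(cfg2, out2)
  expect_true(file.exists(file.path(out2, "survival.csv")))
  sv <- utils::read.csv(file.path(out2, "survival.csv"))
  expect_equal(nrow(sv), 2)
  expect_true(all(sv$pct_surviving >= 0 & sv$pct_surviving <= 100))
})

test_that("bundled recipes load and resolve", {
  recipes <- list.files(system.file("configs", package = "wmnet"),
                        full.names = TRUE)
  expect_gte(length(recipes), 4)
  for (r in recipes) expect_s3_class(load_config(r), "experiment_config")
})
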