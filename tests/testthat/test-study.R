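tiny_config <- function(seed = 1, output_dir = NULL, bad_sample = FALSE) {
  rec <- list(type = "metaphysis",
              args = list(shape = c(24L, 64L, 64L), outer_radius = 21,
                          inner_radius = 16))
  tum <- list(lysis_fraction = 0.8, woven_fraction = 0.3, breach = TRUE,
              band_width = 6)
  samples <- list(
    list(id = "c1", group = "control", recipe = rec),
    list(id = "c2", group = "control", recipe = rec),
    list(id = "t1", group = "tumor",
         recipe = c(rec, list(tumor = tum))),
    list(id = "t2", group = "tumor",
         recipe = c(rec, list(tumor = tum)))
  )
  if (bad_sample)
    samples <- c(samples, list(list(
      id = "broken", group = "tumor",
      recipe = list(type = "metaphysis",
                    args = list(shape = c(24L, 64L, 64L), outer_radius = 10,
                                inner_radius = 5)))))
  study_config(
    samples = samples,
    regions = list(region_spec("proximal", 0, 0.12),
                   region_spec("distal", 12, 0.12)),
    anisotropy = list(n_directions = 32),
    comparisons = list(list(metric = "da", group_x = "control",
                            group_y = "tumor")),
    seed = seed, output_dir = output_dir
  )
}

test_that("study config validates its cross-references", {
  expect_error(study_config(
    samples = list(list(id = "a", group = "g", recipe = list(type = "plate")),
                   list(id = "a", group = "g", recipe = list(type = "plate"))),
    regions = list(region_spec("r", 0, 0.1))), "unique")
  expect_error(study_config(
    samples = list(list(id = "a", group = "g"))), "neither")
  expect_error(study_config(
    samples = list(list(id = "a", group = "g",
                        recipe = list(type = "wedge")))), "unknown phantom")
  base <- list(list(id = "a", group = "g", recipe = list(type = "plate")))
  expect_error(study_config(base, list(region_spec("r", 0, 0.1)),
                            comparisons = list(list(metric = "da",
                                                    group_x = "g",
                                                    group_y = "missing"))),
               "missing group")
  expect_error(study_config(base, list(region_spec("r", 0, 0.1)),
                            comparisons = list(list(metric = "volume",
                                                    group_x = "g",
                                                    group_y = "g"))),
               "unknown comparison metric")
})

test_that("study config round-trips through YAML", {
  cfg <- tiny_config(seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, f)
  cfg2 <- read_study_config(f)
  expect_identical(cfg2$samples, cfg$samples)
  expect_identical(cfg2$seed, cfg$seed)
  expect_identical(cfg2$segmentation, cfg$segmentation)
  expect_identical(lapply(cfg2$regions, unclass),
                   lapply(cfg$regions, unclass))
  expect_identical(cfg2$comparisons, cfg$comparisons)
})

test_that("per-sample seeds depend only on the global seed and the id", {
  s <- list(id = "c1", group = "control",
            recipe = list(type = "metaphysis",
                          args = list(shape = c(12L, 64L, 64L),
                                      outer_radius = 21, inner_radius = 16)))
  v1 <- bonefabric:::build_sample_volume(s, 5)
  v2 <- bonefabric:::build_sample_volume(s, 5)
  expect_identical(v1$values, v2$values)
  v3 <- bonefabric:::build_sample_volume(s, 6)
  expect_false(identical(v1$values, v3$values))
  s2 <- s; s2$id <- "c2"
  v4 <- bonefabric:::build_sample_volume(s2, 5)
  expect_false(identical(v1$values, v4$values))
})

test_that("run_study measures each sample and region deterministically", {
  cfg <- tiny_config(seed = 3)
  r1 <- suppressWarnings(suppressMessages(run_study(cfg)))
  expect_identical(nrow(r1$results), 8L)   # 4 samples x 2 regions
  expect_identical(nrow(r1$failures), 0L)
  expect_true(all(c("bvtv", "conn_d", "euler", "da", "mil_l1",
                    "param_hash") %in% names(r1$results)))
  expect_identical(nrow(r1$comparisons), 2L)  # one metric x two regions
  r2 <- suppressWarnings(suppressMessages(run_study(cfg)))
  expect_identical(r1$results, r2$results)
  expect_identical(r1$comparisons, r2$comparisons)
  # the compartment rules leave tumor bvtv below control bvtv
  mean_by <- tapply(r1$results$bvtv, r1$results$group, mean)
  expect_lt(mean_by[["tumor"]], mean_by[["control"]])
  expect_s3_class(autoplot(r1), "ggplot")
  expect_identical(tidy(r1), r1$results)
  expect_identical(glance(r1)$n_samples, 4L)
})

test_that("a failing sample is recorded while the run continues", {
  cfg <- tiny_config(seed = 3, bad_sample = TRUE)
  r <- suppressWarnings(suppressMessages(run_study(cfg)))
  expect_identical(nrow(r$failures), 1L)
  expect_identical(r$failures$sample, "broken")
  expect_match(r$failures$error, "inner_radius|honeycomb")
  expect_identical(nrow(r$results), 8L)
})

test_that("run_study writes deterministic CSV and JSON outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg1 <- tiny_config(seed = 4, output_dir = d1)
  cfg2 <- tiny_config(seed = 4, output_dir = d2)
  suppressWarnings(suppressMessages(run_study(cfg1)))
  suppressWarnings(suppressMessages(run_study(cfg2)))
  for (f in c("results.csv", "comparisons.csv", "results.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("the CLI front end drives the pipeline", {
  d <- withr::local_tempdir()
  vol_path <- file.path(d, "phantom.nii.gz")
  ph <- run_cli(c("phantom", "--type", "boolean", "--out", vol_path,
                  "--seed", "2", "--shape", "24,24,24"))
  expect_true(file.exists(vol_path))
  seg_path <- file.path(d, "mask.nii.gz")
  run_cli(c("segment", "--in", vol_path, "--out", seg_path))
  expect_true(file.exists(seg_path))
  csv_path <- file.path(d, "measure.csv")
  res <- run_cli(c("measure", "--in", vol_path, "--out", csv_path,
                   "--directions", "32"))
  expect_true(file.exists(csv_path))
  tab <- utils::read.csv(csv_path)
  expect_true(all(c("bvtv", "da") %in% names(tab)))
  expect_gte(tab$da, 1)
  # stats subcommand on a results table
  stats_in <- file.path(d, "results.csv")
  utils::write.csv(data.frame(group = rep(c("a", "b"), each = 4),
                              bvtv = c(1:4, 7:10) / 20), stats_in,
                   row.names = FALSE)
  stats_out <- file.path(d, "mw.csv")
  r <- run_cli(c("stats", "--in", stats_in, "--out", stats_out,
                 "--metric", "bvtv", "--group-x", "a", "--group-y", "b"))
  expect_equal(r$statistic, 0)
  expect_error(run_cli(c("explode")), "unknown command")
  expect_output(run_cli(character(0)), "usage: bonefabric")
})
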