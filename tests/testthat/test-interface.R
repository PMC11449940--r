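test_that("interval CSV and JSON round trips preserve every value exactly", {
  ds <- generate_dataset(list(list(label = "AFIB", count = 3),
                              list(label = "PC", count = 2,
                                   params = list(pattern = "bigeminy"))),
                         seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_intervals_csv(ds, csv)
  write_intervals_json(ds, js)
  for (back in list(read_intervals_csv(csv), read_intervals_json(js))) {
    expect_length(back, length(ds))
    for (i in seq_along(ds)) {
      expect_identical(back[[i]]$intervals, ds[[i]]$intervals)
      expect_identical(back[[i]]$label, ds[[i]]$label)
      expect_identical(back[[i]]$measurement_id, ds[[i]]$measurement_id)
    }
  }
})

test_that("configs default completely and reject unknown keys", {
  cfg <- load_config(NULL)
  expect_identical(cfg, default_config())
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"classifier": {"rounds": 5}}', path)
  cfg <- load_config(path)
  expect_equal(cfg$classifier$rounds, 5)
  expect_equal(cfg$classifier$max_depth, default_config()$classifier$max_depth)
  writeLines('{"clasifier": {"rounds": 5}}', path)
  expect_error(load_config(path), regexp = "clasifier",
               class = "afib_bad_config")
  writeLines('{"simulate": {"n_afi": 1}}', path)
  expect_error(load_config(path), class = "afib_bad_config")
})

test_that("the CLI chain simulate -> train -> classify -> evaluate runs seeded", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.json")
  writeLines(paste0('{"simulate": {"n_afib": 40, "n_sinus": 20,',
                    '"n_pc_bigeminy": 10, "n_pc_random": 10},',
                    '"classifier": {"rounds": 10}}'), cfgp)
  iv <- file.path(dir, "train.csv")
  expect_equal(cli_main(c("simulate", "--config", cfgp, "--seed", "5",
                          "--output", iv)), 0L)
  manifest <- jsonlite::read_json(paste0(iv, ".manifest.json"))
  expect_equal(manifest$seed, 5)
  expect_identical(manifest$checksum_md5, unname(unlist(tools::md5sum(iv))))
  ## same seed regenerates byte-identically
  iv2 <- file.path(dir, "train2.csv")
  cli_main(c("simulate", "--config", cfgp, "--seed", "5", "--output", iv2))
  expect_identical(readLines(iv), readLines(iv2))

  model <- file.path(dir, "model.json")
  expect_equal(cli_main(c("train", "--config", cfgp, "--seed", "5",
                          "--input", iv, "--output", model)), 0L)
  model2 <- file.path(dir, "model2.json")
  cli_main(c("train", "--config", cfgp, "--seed", "5", "--input", iv,
             "--output", model2))
  expect_identical(readLines(model), readLines(model2))

  test_iv <- file.path(dir, "test.csv")
  cli_main(c("simulate", "--config", cfgp, "--seed", "6",
             "--output", test_iv))
  pred <- file.path(dir, "pred.csv")
  expect_equal(cli_main(c("classify", "--model", model, "--input", test_iv,
                          "--output", pred)), 0L)
  p <- read.csv(pred, stringsAsFactors = FALSE)
  expect_equal(nrow(p), 80)               # one row per input measurement

  truth <- file.path(dir, "truth.csv")
  ds <- read_intervals_csv(test_iv)
  write.csv(data.frame(measurement_id = vapply(ds, `[[`, "", "measurement_id"),
                       label = vapply(ds, `[[`, "", "label")),
            truth, row.names = FALSE)
  repjson <- file.path(dir, "report.json")
  expect_equal(suppressMessages(
    cli_main(c("evaluate", "--predictions", pred, "--truth", truth,
               "--output", repjson))), 0L)
  rj <- jsonlite::read_json(repjson)
  expect_true(rj$strata$all$sensitivity$point >= 0)
})

test_that("CLI failure paths exit nonzero with a message", {
  expect_message(st <- cli_main(c("frobnicate")), "unknown subcommand")
  expect_equal(st, 1L)
  expect_message(st <- cli_main(c("train", "--input", "x.csv")),
                 "missing required flag")
  expect_equal(st, 1L)
  ## single-class training input fails loudly
  dir <- withr::local_tempdir()
  iv <- file.path(dir, "one.csv")
  write_intervals_csv(generate_dataset(list(list(label = "AFIB",
                                                 count = 5)), seed = 2), iv)
  expect_message(st <- cli_main(c("train", "--input", iv, "--output",
                                  file.path(dir, "m.json"))),
                 "both classes")
  expect_equal(st, 1L)
  ## zero-measurement request is a config error
  cfgp <- file.path(dir, "cfg.json")
  writeLines(paste0('{"simulate": {"n_afib": 0, "n_sinus": 0,',
                    '"n_pc_bigeminy": 0, "n_pc_random": 0}}'), cfgp)
  expect_message(st <- cli_main(c("simulate", "--config", cfgp,
                                  "--output", file.path(dir, "d.csv"))),
                 "zero measurements")
  expect_equal(st, 1L)
})

test_that("short measurements are flagged INSUFFICIENT, never dropped", {
  dir <- withr::local_tempdir()
  ds <- c(generate_dataset(list(list(label = "SINUS", count = 3)), seed = 3),
          list(ppi_series(rep(0.75, 4), NA, "short_one")))
  iv <- file.path(dir, "mix.csv")
  write_intervals_csv(ds, iv)
  model <- file.path(dir, "model.json")
  save_model(afib_pipeline(small_config(40L, 20L, 10L, 10L), seed = 4)$model,
             model)
  pred <- file.path(dir, "pred.csv")
  cli_main(c("classify", "--model", model, "--input", iv,
             "--output", pred))
  p <- read.csv(pred, stringsAsFactors = FALSE)
  expect_equal(nrow(p), 4)
  expect_equal(p$label[p$measurement_id == "short_one"], "INSUFFICIENT")
  ## a constant-interval measurement classifies as non-AFib
  expect_true(all(p$label[p$measurement_id != "short_one"] == "NON_AFIB"))
})

test_that("one master seed fixes the whole pipeline", {
  cfg <- small_config(40L, 20L, 10L, 10L)
  r1 <- afib_pipeline(cfg, seed = 9)
  r2 <- afib_pipeline(cfg, seed = 9)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_equal(predict(r1$model, r1$test_features)$margin,
               predict(r2$model, r2$test_features)$margin)
})

test_that("the table replay suite passes and flags corrupted constants", {
  checks <- reproduce_tables()
  expect_true(all(checks$pass))
  expect_message(st <- cli_main("reproduce-tables"), "PASS")
  expect_equal(st, 0L)
})
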