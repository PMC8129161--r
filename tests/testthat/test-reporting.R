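write_fixture_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("run_config enforces a single alphabet spec and valid flags", {
  f <- write_fixture_file("1,2,3")
  expect_error(run_config(f), "exactly one alphabet spec")
  expect_error(run_config(f, min_scale = 1, max_scale = 9, preset = "letters"),
               "exactly one alphabet spec")
  expect_error(run_config(f, min_scale = 1, max_scale = 9,
                          measures = character(0)),
               "nothing to compute")
  expect_error(run_config(f, min_scale = 1, max_scale = 9,
                          measures = "Bogus"),
               "unknown measure")
  cfg <- run_config(f, min_scale = 1, max_scale = 9)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$mode, "default")
})

test_that("run_batch produces Table-style layouts and survives bad lines", {
  f <- write_fixture_file(c("1,2,3,4,5,1,2,3,4,5",
                            "1,2,99,4",          # 99 outside the alphabet
                            "5,5,4,4,3,3,2,2,1,1"))
  out_csv <- tempfile(fileext = ".csv")
  cfg <- run_config(f, min_scale = 1, max_scale = 9, rqa = TRUE,
                    measures = c("Redundancy", "NSQ", "TPI", "Adjacency"),
                    out = out_csv, seed = 7)
  res <- run_batch(cfg)

  expect_length(res$errors, 1L)
  expect_match(res$errors, "seq2")
  expect_equal(sort(unique(res$randomization$sequence)), c("seq1", "seq3"))
  expect_setequal(unique(res$randomization$measure),
                  c("Redundancy", "NSQ", "TPI", "Adjacency"))
  expect_equal(names(res$rqa),
               c("sequence", "RR", "DET", "Lmax", "L", "Lentr", "LAM",
                 "Vmax", "TT", "Ventr"))
  expect_equal(nrow(res$rqa), 2L)

  # both tables written; rendered values are 3-decimal strings
  expect_length(res$files, 2L)
  expect_true(all(file.exists(res$files)))
  rng_csv <- utils::read.csv(res$files[["rng"]], stringsAsFactors = FALSE)
  tpi_row <- rng_csv[rng_csv$measure == "TPI" & rng_csv$sequence == "seq1", ]
  expect_equal(as.numeric(tpi_row$value),
               round(tpi(make_sequence(c(1:5, 1:5), min_scale = 1,
                                       max_scale = 9)), 3))
})

test_that("batch output equals concatenated single-sequence runs", {
  lines <- c("1,2,3,4,5,6,7,8,9,1,2,3", "9,8,7,6,5,4,3,2,1,9,8,7",
             "1,1,2,2,3,3,4,4,5,5,6,6")
  f_all <- write_fixture_file(lines)
  cfg_all <- run_config(f_all, min_scale = 1, max_scale = 9, rqa = TRUE,
                        phi_reps = 50, seed = 5)
  res_all <- run_batch(cfg_all)

  singles <- lapply(seq_along(lines), function(k) {
    fk <- write_fixture_file(lines[k])
    r <- run_batch(run_config(fk, min_scale = 1, max_scale = 9, rqa = TRUE,
                              phi_reps = 50, seed = 5))
    r$randomization$sequence <- sprintf("seq%d", k)
    r$rqa$sequence <- sprintf("seq%d", k)
    r
  })
  expect_equal(res_all$randomization,
               do.call(rbind, lapply(singles, `[[`, "randomization")))
  expect_equal(res_all$rqa, do.call(rbind, lapply(singles, `[[`, "rqa")))
})

test_that("json and csv outputs agree and reruns are byte-identical", {
  f <- write_fixture_file(c("1,2,1,2,1,3,4,5,6,7,8,9,1",
                            "3,1,4,1,5,9,2,6,5,3,5,8,9"))
  out_json <- tempfile(fileext = ".json")
  cfg_j <- run_config(f, min_scale = 1, max_scale = 9, format = "json",
                      out = out_json, phi_reps = 50, seed = 3)
  run_batch(cfg_j)
  j1 <- readLines(out_json)
  run_batch(cfg_j)
  expect_identical(readLines(out_json), j1)

  parsed <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  out_csv <- tempfile(fileext = ".csv")
  res_c <- run_batch(run_config(f, min_scale = 1, max_scale = 9,
                                format = "csv", out = out_csv,
                                phi_reps = 50, seed = 3))
  csv_df <- utils::read.csv(out_csv, stringsAsFactors = FALSE,
                            colClasses = "character")
  json_df <- parsed$randomization
  expect_equal(nrow(json_df), nrow(csv_df))
  # full-precision json values round to the rendered csv values
  for (k in seq_len(nrow(csv_df))) {
    jv <- suppressWarnings(as.numeric(json_df$value[k]))
    cv <- suppressWarnings(as.numeric(csv_df$value[k]))
    if (is.na(cv)) expect_true(is.na(jv) || is.null(jv))
    else expect_equal(round(jv, 3), cv, tolerance = 1e-9)
  }
})

test_that("classical mode applies the scaling bridge in batch output", {
  f <- write_fixture_file("1,3,2,4,1,5,2,6,3,7")
  s <- make_sequence(c(1, 3, 2, 4, 1, 5, 2, 6, 3, 7),
                     min_scale = 1, max_scale = 9)
  res <- run_batch(run_config(f, min_scale = 1, max_scale = 9,
                              mode = "classical", measures = "TPI"))
  expect_equal(res$randomization$value, 100 * (tpi(s, "default") + 1))
})

test_that("single_measure mirrors all_rng restricted to one measure", {
  expect_equal(single_measure("coupon", c(1, 2, 3), min_scale = 1,
                              max_scale = 3), 3)
  expect_equal(single_measure("nsq", c(1, 2), min_scale = 1, max_scale = 2), 1)
  expect_equal(single_measure("redundancy", rep(4, 10), min_scale = 1,
                              max_scale = 9, mode = "classical"), 100)
  expect_error(single_measure("bogus", c(1, 2), min_scale = 1, max_scale = 2),
               "valid names")
  r <- single_measure("rqa", c(1, 1, 2, 2, 1, 1, 2, 2), min_scale = 1,
                      max_scale = 2)
  expect_equal(r$TT, 2)
})

test_that("the CLI parses flags, writes output, and reports failures", {
  f <- write_fixture_file(c("1,2,3,4,5,1,2,3,4,5", "2,3,4,5,6,2,3,4,5,6"))
  out <- tempfile(fileext = ".csv")
  status <- rng_cli(c("--min-scale", "1", "--max-scale", "9",
                      "--measures", "Redundancy,TPI,NSQ",
                      "--out", out, "--seed", "4", f))
  expect_equal(status, 0L)
  got <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_setequal(unique(got$measure), c("Redundancy", "TPI", "NSQ"))

  expect_equal(suppressMessages(
    rng_cli(c("--min-scale", "1", "--max-scale", "9",
              file.path(tempdir(), "absent.txt")))), 1L)
  expect_equal(suppressMessages(
    rng_cli(c("--results", "nonsense", "--min-scale", "1", "--max-scale", "9",
              f))), 1L)
})
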