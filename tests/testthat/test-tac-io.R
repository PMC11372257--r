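test_that("frame schedules validate and convert units", {
  sch <- frame_schedule(c(0, 2, 4), c(2, 4, 6))
  expect_equal(sch$mid, c(1, 3, 5) / 60)
  expect_equal(sch$n, 3L)
  expect_error(frame_schedule(c(0, 1), c(1, 1)), "end > start")
  expect_error(frame_schedule(c(0, 0.5), c(1, 1.5)), "overlap")
  expect_error(frame_schedule(c(2, 0), c(3, 1)), "increasing")
  expect_message(frame_schedule(c(0, 10), c(5, 15)), "gaps")

  def <- default_schedule()
  expect_equal(def$n, 65L)
  expect_equal(def$end[def$n], 90)
  expect_equal(def$start[1], 0)
  expect_true(def$contiguous)

  tr <- truncate_schedule(def, 60)
  expect_equal(tr$end[tr$n], 60)
  expect_true(all(tr$end <= 60 + 1e-9))
})

test_that("TAC containers enforce their invariants", {
  expect_error(tac("r", sch_toy, 1:2), "3 frames")
  expect_error(tac("r", sch_toy, c(1, NA, 2)), "non-finite")
  t1 <- tac("r", sch_toy, c(1, -0.2, 2))
  expect_equal(t1$n_negative, 1L)  # negatives allowed, flagged
  expect_error(scan_record("s", "x", list(liver = tac("liver", sch_toy, 1:3))),
               "aorta")
  sch_other <- frame_schedule(c(0, 30), c(30, 60))
  expect_error(scan_record("s", "x", list(
    aorta = tac("aorta", sch_toy, 1:3),
    right_ventricle = tac("right_ventricle", sch_other, 1:2))),
    "share one frame schedule")
})

test_that("TAC tables round-trip bit-for-bit with stable column order", {
  scan <- make_toy_scan()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(scan, path)
  back <- read_tac_table(path, schedule = sch_toy)
  for (r in names(scan$tacs))
    expect_identical(back$tacs[[r]]$values, scan$tacs[[r]]$values)
  expect_identical(back$subject, "s1")

  # blood first, then alphabetical; stable across rewrites
  hdr <- names(read.csv(path, comment.char = "#", check.names = FALSE))
  expect_identical(hdr, c("frame_start", "frame_end", "aorta",
                          "right_ventricle", "liver", "spleen"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(scan, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("TAC tables preserve unit and aggregation metadata", {
  tacs <- list(aorta = tac("aorta", sch_toy, c(5, 3, 2), unit = "kBq/mL"),
               right_ventricle = tac("right_ventricle", sch_toy, c(6, 3, 2),
                                     unit = "kBq/mL"),
               ln_ax = tac("ln_ax", sch_toy, 1:3, unit = "kBq/mL",
                           aggregation = "peak"))
  scan <- scan_record("s2", "pre", tacs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tac_table(scan, path)
  back <- read_tac_table(path)
  expect_identical(back$tacs$ln_ax$aggregation, "peak")
  expect_identical(back$tacs$aorta$aggregation, "mean")
  expect_identical(back$tacs$aorta$unit, "kBq/mL")
  expect_identical(back$scan, "pre")
})

test_that("malformed TAC tables are rejected with informative errors", {
  scan <- make_toy_scan()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(scan, path)
  # frame-count mismatch against an expected schedule
  expect_error(read_tac_table(path, schedule = default_schedule()),
               "does not match")
  # missing blood column
  lines <- readLines(path)
  lines <- sub("aorta", "not_blood", lines)
  writeLines(lines, path)
  expect_error(read_tac_table(path), "aorta")
  # non-numeric cell
  write_tac_table(scan, path)
  lines <- readLines(path)
  lines[7] <- sub("^([0-9.]+),([0-9.]+),([0-9.]+)", "\\1,\\2,oops", lines[7])
  writeLines(lines, path)
  expect_error(read_tac_table(path), "parse error")
})

test_that("round-trip identity holds on randomly generated tables", {
  set.seed(11)
  for (i in 1:5) {
    nfr <- sample(3:12, 1)
    ends <- cumsum(sample(c(2, 10, 60), nfr, replace = TRUE))
    sch <- frame_schedule(c(0, head(ends, -1)), ends)
    regions <- c("aorta", "right_ventricle",
                 paste0("r", sample(letters, sample(1:4, 1))))
    vals <- lapply(regions, function(r) round(rnorm(nfr, 2, 1), 6))
    names(vals) <- regions
    tacs <- lapply(regions, function(r) tac(r, sch, vals[[r]]))
    names(tacs) <- regions
    scan <- scan_record(paste0("s", i), "scan1", tacs)
    path <- withr::local_tempfile(fileext = ".csv")
    write_tac_table(scan, path)
    back <- read_tac_table(path)
    for (r in regions)
      expect_identical(back$tacs[[r]]$values, vals[[r]])
  }
})

test_that("configuration defaults match the analysis constants", {
  cfg <- load_config()
  expect_equal(cfg$t_star, 30)
  expect_equal(cfg$suvr_window, c(60, 90))
  expect_equal(cfg$biexp_window, c(14, 90))
  expect_equal(cfg$horizon, 600)
  expect_equal(cfg$n_reps, 100)
  expect_equal(cfg$seed, 42)  # fixed documented default
})

test_that("configurations load from YAML/JSON and reject bad input", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("t_star: 25\nn_reps: 50", yml)
  cfg <- load_config(yml)
  expect_equal(cfg$t_star, 25)
  expect_equal(cfg$n_reps, 50)
  expect_equal(cfg$horizon, 600)  # untouched default

  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"suvr_window": [50, 80]}', jsn)
  expect_equal(load_config(jsn)$suvr_window, c(50, 80))

  expect_error(load_config(overrides = list(nope = 1)), "unknown config")
  expect_error(load_config(overrides = list(t_star = 95)),
               "before the scan end")
  expect_error(load_config(overrides = list(suvr_window = c(90, 60))),
               "increasing")
  expect_error(load_config(overrides = list(n_reps = 1)), "n_reps")
})
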