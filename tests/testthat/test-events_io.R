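test_that("csv call tables read, validate and sort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "session_id,phase,caller_id,onset_s,offset_s,vocal_type",
    "S1,F2F,B,2.000,2.025,call",
    "S1,F2F,A,1.000,1.025,call"
  ), path)
  ev <- read_call_table(path, dialect = "csv")
  expect_equal(nrow(ev), 2)
  expect_equal(ev$caller_id, c("A", "B"))
  expect_equal(ev$onset, c(1.0, 2.0))
})

test_that("raven selection tables map begin/end times and channels", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Selection\tBegin Time (s)\tEnd Time (s)\tChannel\tAnnotation",
    "1\t1.000\t1.025\t1\tcall",
    "2\t2.500\t2.530\t2\tcall"
  ), path)
  ev <- read_call_table(path, dialect = "raven", session_id = "S1",
                        phase = "F2F",
                        caller_map = c("1" = "birdA", "2" = "birdB"))
  expect_equal(ev$onset, c(1.0, 2.5))
  expect_equal(ev$offset[1], 1.025)
  expect_equal(ev$caller_id, c("birdA", "birdB"))
})

test_that("malformed tables raise informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "session_id,phase,caller_id,onset_s,offset_s,vocal_type",
    "S1,F2F,A,2.0,1.9,call"
  ), path)
  expect_error(read_call_table(path), "offset must exceed onset.*1")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "session_id,phase,caller_id,onset_s,offset_s",
    "S1,F2F,A,1.0,1.1"
  ), path2)
  expect_error(read_call_table(path2), "vocal_type")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "session_id,phase,caller_id,onset_s,offset_s,vocal_type",
    "S1,DUET,A,1.0,1.1,call"
  ), path3)
  expect_error(read_call_table(path3), "unknown phase")

  expect_error(read_call_table("no/such/file.csv"), "not found")
})

test_that("write/read round-trips events to 1 ms and reading is order-insensitive", {
  withr::local_seed(42)
  n <- 40
  onsets <- sort(runif(n, 0, 890))
  ev <- make_events(onsets, sample(c("A", "B"), n, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_call_table(ev, path)
  back <- read_call_table(path)
  expect_equal(back$onset, round(ev$onset, 3))
  expect_equal(back$offset, round(ev$offset, 3))
  expect_equal(back$caller_id, ev$caller_id)

  # shuffle the data rows; the sorted result must be identical
  lines <- readLines(path)
  shuffled <- c(lines[1], sample(lines[-1]))
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, path2)
  expect_equal(read_call_table(path2), back)
})

test_that("filter_events selects by type and phase, preserving order", {
  ev <- validate_call_events(rbind(
    make_events(c(1, 3), "A", phase = "F2F"),
    make_events(2, "A", phase = "F2F", vocal_type = "song"),
    make_events(c(1.5, 4), "A", phase = "PRE"),
    make_events(5, "A", phase = "POST", vocal_type = "trill")
  ))
  f2f_calls <- filter_events(ev, vocal_type = "call", phase = "F2F")
  expect_equal(f2f_calls$onset, c(1, 3))
  expect_equal(nrow(filter_events(ev, "call", "PRE")), 2)
  expect_equal(nrow(filter_events(make_events(1, "A", phase = "PRE"),
                                  "call", "F2F")), 0)
  # order preserved from the sorted input
  expect_equal(filter_events(ev, "call", "PRE")$onset, c(1.5, 4))
})

test_that("session records enforce solo-phase caller identity", {
  ev <- rbind(make_events(1, "A", phase = "PRE"),
              make_events(c(2, 3), c("A", "B"), phase = "F2F"))
  rec <- session_record("S1", "A", "B", ev)
  expect_s3_class(rec, "session_record")
  bad <- rbind(make_events(1, "B", phase = "PRE"),
               make_events(2, "A", phase = "F2F"))
  expect_error(session_record("S1", "A", "B", bad), "subject")
  expect_error(session_record("S1", "A", "B",
                              make_events(1, "C", phase = "F2F")),
               "outside the pair")
})
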