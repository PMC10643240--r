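test_that("a hand-written minimal record round-trips through read_record", {
  d <- withr::local_tempdir()
  writeLines(c("time_s,rr_ms,sbp_mmHg,dbp_mmHg,qt_s,st_nu",
               "1,1000,120,80,0.4,0.1",
               "2,1000,118,78,,"),
             file.path(d, "beats.csv"))
  writeLines(fmt <- rep("0", 60), file.path(d, "flow.txt"))
  writeLines('{"fs_hz": 20}', file.path(d, "flow.json"))
  writeLines(paste0('{"subject_id":"mini","weight_kg":73,"height_cm":178,',
                    '"sinus_rhythm":true,"segments":[',
                    '{"label":"SR","start":0,"end":1},',
                    '{"label":"CR6","start":1,"end":2},',
                    '{"label":"CR15","start":2,"end":3}]}'),
             file.path(d, "meta.json"))
  rec <- read_record(d)
  expect_s3_class(rec, "subject_record")
  expect_equal(nrow(rec$beats), 2L)
  expect_equal(rec$beats$qt, c(0.4, NA))
  expect_equal(rec$flow$fs, 20)
})

test_that("write/read round-trip is the identity and re-writing is byte-identical", {
  out <- generate_subject(sim_config(seed = 7))
  rec <- out$record
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_record(rec, d1)
  rec2 <- read_record(d1)
  expect_equal(rec2$subject_id, rec$subject_id)
  expect_equal(as.data.frame(rec2$beats), as.data.frame(rec$beats))
  expect_equal(rec2$flow$samples, rec$flow$samples)
  expect_equal(rec2$flow$fs, rec$flow$fs)
  expect_equal(as.data.frame(rec2$segments), as.data.frame(rec$segments))
  expect_equal(rec2$weight_kg, rec$weight_kg)
  write_record(rec2, d2)
  for (f in c("beats.csv", "flow.txt", "flow.json", "meta.json")) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
  # simulator output read back keeps the emitted beat count
  expect_equal(nrow(rec2$beats), nrow(rec$beats))
})

test_that("absent optional annotations are omitted on disk and restored as NA", {
  b <- make_regular_beats(3, 1000)           # no qt/st/sv annotations
  rec <- make_tiny_record(beats = b, duration = 10)
  rec$segments <- segment_markers(c(0, 4, 7), c(4, 7, 10))
  d <- withr::local_tempdir()
  write_record(rec, d)
  hdr <- readLines(file.path(d, "beats.csv"), n = 1)
  expect_identical(hdr, "time_s,rr_ms,sbp_mmHg,dbp_mmHg,qt_s,st_nu")
  rec2 <- read_record(d)
  expect_true(all(is.na(rec2$beats$qt)))
  expect_true(all(is.na(rec2$beats$sv)))
})

test_that("validation rejects broken beat tables with the offending index", {
  expect_error(
    beat_series(c(1, 3, 2), rep(1000, 3), rep(120, 3), rep(80, 3)),
    "index: 3")
  expect_error(
    beat_series(c(1, 2), c(1000, 1000), c(120, 70), c(80, 80)),
    "sbp > dbp")
  expect_error(
    beat_series(c(1, 2.5), c(1000, 1000), c(120, 120), c(80, 80)),
    "disagree")
  d <- withr::local_tempdir()
  expect_error(read_record(d), "missing channel")
})

test_that("epoch slicing follows the half-open, full-containment convention", {
  rec <- make_tiny_record(rr_ms = 1000)
  sr <- slice_epoch(rec, "SR")
  # beats at t = 1..119 s: 119 fully-contained 1-s intervals
  expect_equal(nrow(sr$beats), 119L)
  expect_true(all(!is.na(sr$beats$rr)))
  # a beat exactly at the window end is excluded
  expect_false(120 %in% sr$beats$time)
  # the first CR6 beat's interval starts at 119 s, outside [120, 240): rr NA
  cr6 <- slice_epoch(rec, "CR6")
  expect_true(is.na(cr6$beats$rr[1L]))
  expect_false(any(is.na(cr6$beats$rr[-1L])))
  expect_error(slice_epoch(rec, "CR9"), "no segment labelled")
})

test_that("epoch slicing partitions every beat exactly once", {
  rec <- generate_subject(sim_config(seed = 12))$record
  times <- unlist(lapply(rec$segments$label,
                         function(l) slice_epoch(rec, l)$beats$time))
  expect_identical(sort(times), rec$beats$time)
})
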