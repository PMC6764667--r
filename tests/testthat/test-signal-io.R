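test_that("canonical text format round-trips bit-exactly", {
  set.seed(42)
  ch <- channel_recording(rnorm(10), rate = 300, label = "abp",
                          units = "mmHg", t0 = 1.25)
  f <- withr::local_tempfile(fileext = ".txt")
  write_channel_text(ch, f)
  back <- read_channel_text(f)
  expect_identical(back$samples, ch$samples)
  expect_identical(back$rate, ch$rate)
  expect_identical(back$t0, ch$t0)
  expect_identical(back$label, ch$label)
  expect_identical(back$units, ch$units)
})

test_that("two-column dialect infers the rate from the time step", {
  f <- withr::local_tempfile(fileext = ".txt")
  t <- (0:399) / 400
  writeLines(sprintf("%.10f\t%.6f", t, sin(t)), f)
  ch <- read_channel_text(f, dialect = "two_column")
  expect_equal(ch$rate, 400, tolerance = 1e-9)
  expect_equal(ch$t0, 0)
  expect_length(ch$samples, 400)
})

test_that("malformed channel files raise parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".txt")
  # gap in the time column
  t <- c((0:9) / 100, 0.2 + (0:9) / 100)
  writeLines(sprintf("%.6f,%.4f", t, seq_along(t)), f)
  expect_error(read_channel_text(f, dialect = "two_column"), "line 11")
  # non-monotone time
  writeLines(c("0,1", "0.01,2", "0.005,3"), f)
  expect_error(read_channel_text(f, dialect = "two_column"), "non-monotone")
  # missing header field
  writeLines(c("# label: x", "# rate: 100", "# t0: 0", "1", "2"), f)
  expect_error(read_channel_text(f), "units")
  # non-numeric sample
  writeLines(c("# label: x", "# rate: 100", "# units: a.u.", "# t0: 0",
               "1", "oops", "3"), f)
  expect_error(read_channel_text(f), "line 6")
})

test_that("synchronize crops channels to their common overlap", {
  a <- channel_recording(rep(1, 1001), 10, "a", t0 = 0)    # [0, 100]
  b <- channel_recording(rep(2, 1101), 10, "b", t0 = 10)   # [10, 120]
  ds <- synchronize(list(a, b))
  expect_equal(ds$span, c(10, 100))
  expect_equal(ds$channels$a$t0, 10)
  expect_equal(channel_end(ds$channels$b), 100)

  same <- synchronize(list(a = a))
  expect_equal(same$channels$a$samples, a$samples)

  expect_error(synchronize(list(a, b), span = c(105, 130)), "outside")
  c2 <- channel_recording(1:10, 10, "c", t0 = 500)
  expect_error(synchronize(list(a, c2)), "overlap")
})

test_that("resample preserves DC, low-frequency amplitude and identity", {
  const <- channel_recording(rep(7.5, 4001), 400, "cvp", "mmHg")
  down <- resample_channel(const, 40)
  expect_equal(down$rate, 40)
  expect_equal(down$samples, rep(7.5, length(down$samples)), tolerance = 1e-9)

  s <- sin_channel(0.25, 60, 400, amp = 2, mean = 6)
  d <- resample_channel(s, 40)
  expect_equal(max(d$samples) - min(d$samples), 4, tolerance = 0.04)

  expect_identical(resample_channel(s, 400), s)
})

test_that("resample is linear in its input", {
  set.seed(7)
  x <- channel_recording(rnorm(2000), 400, "x")
  y <- channel_recording(rnorm(2000), 400, "y")
  comb <- channel_recording(2 * x$samples - 3 * y$samples, 400, "z")
  lhs <- resample_channel(comb, 40)$samples
  rhs <- 2 * resample_channel(x, 40)$samples - 3 * resample_channel(y, 40)$samples
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("extract_segment uses half-open intervals with exact lengths", {
  ch <- channel_recording(seq_len(300 * 60 + 1), 300, "abp", "mmHg")
  ds <- synchronize(list(ch))
  seg <- extract_segment(ds, list(start = 10, end = 40, subject = "S01",
                                  lbnp = 20, intervention = "PEP",
                                  resistance = 5))
  expect_length(seg$channels$abp$samples, 9000)
  expect_equal(seg$meta$subject, "S01")

  full <- extract_segment(ds, list(start = 0, end = 60 + 1 / 300))
  expect_length(full$channels$abp$samples, length(ch$samples))

  expect_error(extract_segment(ds, list(start = 5, end = 5)), "end > start")
  expect_error(extract_segment(ds, list(start = 50, end = 70)), "outside")
})

test_that("protocol annotations validate levels and overlap, round-trip as JSON", {
  ann <- protocol_annotation(c("S01", "S01"), c(0, 30), c(30, 60),
                             c(0, 20), c("PEP", "PEP"), c(0, 5))
  f <- withr::local_tempfile(fileext = ".json")
  write_protocol_json(ann, f)
  back <- read_protocol_json(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))

  expect_error(protocol_annotation("S01", 0, 30, 15, "PEP", 0), "lbnp")
  expect_error(protocol_annotation("S01", 0, 30, 20, "BIPAP", 0), "intervention")
  expect_error(protocol_annotation("S01", 0, 30, 20, "PEP", 7), "resistance")
  expect_error(
    protocol_annotation(c("S01", "S01"), c(0, 20), c(30, 50), c(0, 20),
                        c("PEP", "PEP"), c(0, 5)),
    "overlap")
})
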