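test_that("csv record parsing reads header metadata and samples", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs: 250", "# channels: MLII,V5", "# units: mV,mV",
               paste(seq(0, 0.9, by = 0.1), seq(10, 19), sep = ",")), p)
  rec <- read_record(p, "csv")
  expect_equal(n_channels(rec), 2)
  expect_equal(n_samples(rec), 10)
  expect_equal(rec$fs, 250)
  expect_equal(rec$channel_names, c("MLII", "V5"))
  expect_equal(channel(rec, "V5"), 10:19, tolerance = 0)
})

test_that("csv record round trip preserves samples bit-exactly", {
  rec <- ecg_record(matrix(rnorm(40), ncol = 2), fs = 360,
                    channel_names = c("a", "b"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, p, "csv")
  back <- read_record(p, "csv")
  expect_identical(back$samples, rec$samples)
  expect_identical(back$fs, rec$fs)
})

test_that("csv record errors are informative", {
  p <- withr::local_tempfile(fileext = ".csv")
  expect_error(read_record(p, "csv"), "not found")
  writeLines(c("0.1,0.2", "0.3,0.4"), p)           # fs missing
  expect_error(read_record(p, "csv"), "fs")
  writeLines(c("# fs: 250", "0.1,0.2", "0.3"), p)  # ragged rows
  expect_error(read_record(p, "csv"), "inconsistent")
})

test_that("a hand-built wfdb format-212 record is read correctly", {
  # two channels, 4 samples each, fs = 360, gain 200, baseline 0;
  # .dat bytes packed by hand, independent of the package writer
  dir <- withr::local_tempdir()
  adc1 <- c(100L, -100L, 2047L, -2048L)
  adc2 <- c(0L, 50L, -50L, 7L)
  pack212 <- function(a, b) {
    a12 <- a %% 4096L; b12 <- b %% 4096L
    as.raw(c(a12 %% 256L, (b12 %/% 256L) * 16L + a12 %/% 256L, b12 %% 256L))
  }
  bytes <- raw(0)
  for (i in 1:4) bytes <- c(bytes, pack212(adc1[i], adc2[i]))
  writeBin(bytes, file.path(dir, "toy.dat"))
  writeLines(c("toy 2 360 4",
               "toy.dat 212 200(0)/mV 12 0 0 0 0 MLII",
               "toy.dat 212 200(0)/mV 12 0 0 0 0 V5"),
             file.path(dir, "toy.hea"))
  rec <- read_record(file.path(dir, "toy.hea"), "wfdb")
  expect_equal(rec$fs, 360)
  expect_equal(n_samples(rec), 4)
  expect_equal(channel(rec, 1), adc1 / 200)
  expect_equal(channel(rec, 2), adc2 / 200)
  expect_equal(rec$channel_names, c("MLII", "V5"))
})

test_that("wfdb record write/read round trip preserves quantized samples", {
  rec <- ecg_record(matrix(round(rnorm(60), 2), ncol = 2), fs = 250)
  dir <- withr::local_tempdir()
  write_record(rec, file.path(dir, "rt.hea"), "wfdb")
  back <- read_record(file.path(dir, "rt"), "wfdb")
  # writer quantizes at 200 adu/mV; samples at 0.01 mV resolution survive
  expect_equal(back$samples, rec$samples, tolerance = 1 / 200 + 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$fs, 250)
})

test_that("csv annotations parse, order and round trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("100,Qon", "130,Rpeak", "165,Soff"), p)
  ann <- read_annotations(p, "csv")
  expect_equal(nrow(ann), 3)
  expect_equal(ann$label, c("Qon", "Rpeak", "Soff"))
  expect_equal(ann$sample_index, c(101L, 131L, 166L))  # disk is 0-based

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, p2, "csv")
  expect_identical(read_annotations(p2, "csv"), ann)

  writeLines(character(0), p2)
  expect_equal(nrow(read_annotations(p2, "csv")), 0)

  writeLines("-5,Qon", p2)
  expect_error(read_annotations(p2, "csv"), "negative")
})

test_that("wfdb annotation round trip preserves entries across SKIP escapes", {
  ann <- annotation_set(c(10, 500, 5000, 90000, 90100),
                        c("Qon", "Rpeak", "Soff", "Rpeak", "Soff"))
  p <- withr::local_tempfile(fileext = ".atr")
  write_annotations(ann, p, "wfdb")
  back <- read_annotations(p, "wfdb")
  expect_identical(back$sample_index, ann$sample_index)
  expect_identical(back$label, ann$label)
})
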