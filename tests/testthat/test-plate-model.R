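test_that("write_plate/read_plate round-trips simulator output", {
  sim <- simulate_plate(simulation_design(),
                        list(a = archetype_params("cytotoxic"),
                             b = archetype_params("dna_damaging")),
                        seed = 11)
  td <- withr::local_tempdir()
  ts_path <- file.path(td, "ts.csv")
  lay_path <- file.path(td, "layout.csv")
  write_plate(sim$plate, ts_path, lay_path)
  back <- read_plate(ts_path, lay_path, plate_id = sim$plate$plate_id)
  expect_identical(back$layout, sim$plate$layout)
  expect_identical(colnames(back$values), colnames(sim$plate$values))
  expect_equal(back$times, sim$plate$times, tolerance = 1e-9)
  expect_lt(max(abs(back$values - sim$plate$values) /
                  pmax(abs(sim$plate$values), 1e-12)), 1e-9)
  expect_equal(back$dose_times, sim$plate$dose_times)
})

test_that("a full 96-well plate writes 96 data columns plus time", {
  cmpds <- lapply(1:7, function(i) archetype_params("cytotoxic"))
  names(cmpds) <- paste0("c", 1:7)  # 7*12 + 6 vehicle + 6 positive = 96
  sim <- simulate_plate(simulation_design(), cmpds, seed = 2)
  td <- withr::local_tempdir()
  write_plate(sim$plate, file.path(td, "ts.csv"), file.path(td, "lay.csv"))
  hdr <- strsplit(readLines(file.path(td, "ts.csv"), n = 1L), ",")[[1L]]
  expect_length(hdr, 97L)
  expect_identical(hdr[1L], "time_h")
})

test_that("identical design and seed give byte-identical written files", {
  td <- withr::local_tempdir()
  for (run in 1:2) {
    sim <- simulate_plate(simulation_design(),
                          list(a = archetype_params("antimitotic")),
                          seed = 99)
    write_plate(sim$plate, file.path(td, sprintf("ts%d.csv", run)),
                file.path(td, sprintf("lay%d.csv", run)))
  }
  expect_identical(readLines(file.path(td, "ts1.csv")),
                   readLines(file.path(td, "ts2.csv")))
  expect_identical(readLines(file.path(td, "lay1.csv")),
                   readLines(file.path(td, "lay2.csv")))
})

test_that("malformed inputs raise typed, named errors (never partial parses)", {
  td <- withr::local_tempdir()
  ts_path <- file.path(td, "ts.csv")
  lay_path <- file.path(td, "lay.csv")
  lay <- paste(c("well,role,compound_id,concentration_uM,replicate_index,dose_times",
                 "A01,vehicle_control,,,1,1",
                 "B01,treated,drug,10,1,"), collapse = "\n")
  writeLines(lay, lay_path)

  # layout well absent from the time-series file, named in the error
  writeLines(c("time_h,B01", "0,1", "1,2", "2,3"), ts_path)
  expect_error(read_plate(ts_path, lay_path), "A01")

  # non-increasing time column
  writeLines(c("time_h,A01,B01", "0,1,1", "1,2,2", "1,3,3"), ts_path)
  expect_error(read_plate(ts_path, lay_path), "non-increasing time")

  # wrong header
  writeLines(c("hours,A01,B01", "0,1,1", "1,2,2"), ts_path)
  expect_error(read_plate(ts_path, lay_path), "time_h")

  expect_error(read_plate(file.path(td, "nope.csv"), lay_path), "not found")
})

test_that("plate construction enforces layout invariants", {
  times <- 0:5
  vals <- cbind(A01 = 1:6, A02 = 2:7)
  lay <- data.frame(well = c("A01", "A02"),
                    role = c("treated", "vehicle_control"),
                    compound_id = c("x", NA), concentration_uM = c(1, NA),
                    replicate_index = c(1, 1), stringsAsFactors = FALSE)
  expect_s3_class(rtca_plate(times, vals, lay, 2), "rtca_plate")

  bad <- lay; bad$role <- c("treated", "treated")
  bad$compound_id <- "x"; bad$concentration_uM <- 1
  expect_error(rtca_plate(times, vals, bad, 2), "vehicle_control")

  bad <- lay; bad$compound_id[1] <- NA
  expect_error(rtca_plate(times, vals, bad, 2), "compound_id")

  bad <- lay; bad$concentration_uM[2] <- 5
  expect_error(rtca_plate(times, vals, bad, 2), "vehicle_control wells")

  expect_error(rtca_plate(times, vals, lay, 99), "dose time")
  expect_error(rtca_plate(times, vals[, 1, drop = FALSE], lay, 2),
               "absent from time-series")
})

test_that("trace constructor validates grids and dose times", {
  expect_error(rtca_trace(c(0, 1, 1), c(1, 2, 3)), "non-increasing")
  expect_error(rtca_trace(0:2, 1:2), "equal length")
  expect_error(rtca_trace(0:2, 1:3, dose_time = 5), "outside")
  expect_error(rtca_trace(0:2, 1:3, well = "Z99"), "invalid well")
  expect_identical(well_address("B", 7), "B07")
  expect_error(well_address("I", 1), "A-H")
})

test_that("labels files parse with typed booleans and mechanisms", {
  td <- withr::local_tempdir()
  p <- file.path(td, "labels.csv")
  writeLines(c("compound_id,genotoxic_reference,mechanism_reference",
               "a,true,dna_damaging", "b,false,", "c,,antimitotic"), p)
  lab <- read_labels(p)
  expect_identical(lab$genotoxic_reference, c(TRUE, FALSE, NA))
  expect_identical(lab$mechanism_reference,
                   c("dna_damaging", NA, "antimitotic"))
  writeLines(c("compound_id,genotoxic_reference,mechanism_reference",
               "a,true,warp_drive"), p)
  expect_error(read_labels(p), "warp_drive")
})
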