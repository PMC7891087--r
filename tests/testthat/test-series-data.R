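test_that("canonical CSV parses into per-specimen series, dropping blank lengths as gaps", {
  path <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm",
    "A,Examplesaurus,1,30", "A,Examplesaurus,2,28", "A,Examplesaurus,3,26"
  ))
  series <- read_series_table(path)
  expect_length(series, 1)
  expect_equal(series[["A"]]$positions, c(1, 2, 3))
  expect_equal(series[["A"]]$lengths, c(30, 28, 26))
  expect_true(is.na(series[["A"]]$transition_point))

  gapped <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm",
    "A,Examplesaurus,1,30", "A,Examplesaurus,2,", "A,Examplesaurus,3,26"
  ))
  expect_message(series <- read_series_table(gapped), "dropped 1 row")
  expect_equal(series[["A"]]$positions, c(1, 3))
})

test_that("transition point is the last vertebra flagged with a lateral process", {
  rows <- sprintf("TMP98,Hadrosauridae,%d,%0.1f,%s", 1:20,
                  kink_profile(1:20, 35, 12, c(-1.5, 0.5)),
                  c(rep("TRUE", 12), rep("FALSE", 8)))
  path <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm,has_lateral_process", rows))
  series <- read_series_table(path)
  expect_equal(series[["TMP98"]]$transition_point, 12)
})

test_that("master-layout headers are mapped onto the canonical schema", {
  path <- write_tmp_csv(c(
    "Specimen,Taxon,Caudal number,Length (mm),Lateral process",
    "B,Testosaurus,1,22.5,yes", "B,Testosaurus,2,21.0,yes", "B,Testosaurus,3,20.1,no",
    "B,Testosaurus,4,19.0,no", "B,Testosaurus,5,18.2,no"
  ))
  series <- read_series_table(path, format = "master")
  expect_equal(series[["B"]]$positions, 1:5)
  expect_equal(series[["B"]]$transition_point, 2)
})

test_that("schema and row-level validation errors name the offender", {
  no_col <- write_tmp_csv(c("specimen_id,taxon,vertebra_number", "A,T,1"))
  expect_error(read_series_table(no_col), "centrum_length_mm",
               class = "caudseg_schema_error")

  bad_len <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm",
    "A,T,1,30", "A,T,2,-4", "A,T,3,26"
  ))
  expect_error(read_series_table(bad_len), "row", class = "caudseg_validation_error")

  dup <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm",
    "A,T,1,30", "A,T,1,29", "A,T,3,26"
  ))
  expect_error(read_series_table(dup), "duplicated",
               class = "caudseg_validation_error")
})

test_that("write/read round-trips series field-for-field, gaps and all", {
  s1 <- caudal_series("X1", "Taxon one", c(1, 2, 4, 6, 7), c(30, 28, 25, 21, 20),
                      clade = "CladeA", transition_point = 4, complete = TRUE)
  s2 <- caudal_series("X2", "Taxon two", 1:6, c(12, 11, 10.5, 9, 8.5, 8))
  path <- tempfile(fileext = ".csv")
  write_series_table(list(s1, s2), path)
  back <- read_series_table(path)
  expect_equal(back[["X1"]]$positions, s1$positions)
  expect_equal(back[["X1"]]$lengths, s1$lengths)
  expect_equal(back[["X1"]]$transition_point, 4)
  expect_equal(back[["X2"]]$lengths, s2$lengths)
  expect_true(is.na(back[["X2"]]$transition_point))

  empty <- tempfile(fileext = ".csv")
  write_series_table(list(), empty)
  expect_equal(nrow(read.csv(empty)), 0)
})

test_that("parsing sorts vertebrae ascending regardless of row order", {
  path <- write_tmp_csv(c(
    "specimen_id,taxon,vertebra_number,centrum_length_mm",
    "A,T,3,26", "A,T,1,30", "A,T,2,28"
  ))
  s <- read_series_table(path)[["A"]]
  expect_equal(s$positions, c(1, 2, 3))
  expect_equal(s$lengths, c(30, 28, 26))
})

test_that("caudal_series enforces its invariants", {
  expect_error(caudal_series("A", "T", c(1, 1, 2), c(1, 2, 3)),
               "strictly increasing", class = "caudseg_validation_error")
  expect_error(caudal_series("A", "T", 1:3, c(1, -2, 3)),
               class = "caudseg_validation_error")
  expect_error(caudal_series("A", "T", 1:3, c(1, 2, 3), transition_point = 9),
               "transition_point", class = "caudseg_validation_error")
})

test_that("specimen table parses, validates locomotor class, defaults the largest flag", {
  path <- write_tmp_csv(c(
    "specimen_id,taxon,femur_mm,snout_sacrum_mm,tail_mm,locomotor_class",
    "SCUT,Scutellosaurus,82,405,721.6,biped",
    "EPI,Epidexipteryx,55,158,66,biped"
  ))
  rec <- read_specimen_table(path)
  expect_equal(rec$femur_mm[rec$specimen_id == "SCUT"], 82)
  expect_false(any(rec$largest_of_species))

  bad <- write_tmp_csv(c(
    "specimen_id,taxon,femur_mm,locomotor_class",
    "A,T,100,hopper"
  ))
  expect_error(read_specimen_table(bad), "locomotor_class",
               class = "caudseg_validation_error")
})
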