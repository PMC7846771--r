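# Peak list parsing, validation and round-tripping.

write_lines_tmp <- function(...) {
  f <- tempfile()
  writeLines(c(...), f)
  f
}

test_that("native HMQC lists parse with annotations and validate links", {
  f <- write_lines_tmp(
    "peak_id c h types stereo geminal fixed",
    "1 24.5 0.85 LV proS 2 -",
    "2 23.9 0.70 LV - 1 -",
    "3 13.1 0.60 I - - I12CD1")
  pk <- read_hmqc(f)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$geminal_partner, c(2L, 1L, NA))
  expect_equal(pk$stereo, c("proS", "unknown", "unknown"))
  expect_equal(pk$allowed_types, c("LV", "LV", "I"))
  expect_equal(pk$fixed_assignment, c(NA, NA, "I12CD1"))

  # geminal partner missing from the list
  bad <- write_lines_tmp("h", "1 24.5 0.85 LV - 9 -")
  expect_error(read_hmqc(bad), "does not exist")
  # non-mutual link
  bad2 <- write_lines_tmp("h", "1 24.5 0.85 LV - 2 -", "2 23.9 0.7 LV - -")
  expect_error(read_hmqc(bad2), "non-mutual")
  # duplicate ids
  bad3 <- write_lines_tmp("h", "1 24.5 0.85", "1 23.9 0.7")
  expect_error(read_hmqc(bad3), "duplicate")
  # geminal pair on a non-Leu/Val peak
  bad4 <- write_lines_tmp("h", "1 24.5 0.85 I - 2 -", "2 23.9 0.7 I - 1 -")
  expect_error(read_hmqc(bad4), "Leu/Val")
  # malformed annotation reports the line
  bad5 <- write_lines_tmp("h", "1 24.5 0.85 QX")
  expect_error(read_hmqc(bad5), "line 2")
})

test_that("sparky dialect reads label + w1/w2 columns", {
  f <- write_lines_tmp("      Assignment     w1     w2",
                       "       L45CD1-HD1  24.51  0.845",
                       "                ?  21.02  0.801")
  pk <- read_hmqc(f, dialect = "sparky")
  expect_equal(pk$peak_id, 1:2)
  expect_equal(pk$c_shift, c(24.51, 21.02))
  expect_true(all(pk$allowed_types == "any"))
})

test_that("NOESY lists parse 3D and 4D rows and tag mixing class", {
  f <- write_lines_tmp("c1 c2 h2", "10.1 24.5 0.83", "25 13.2 0.61")
  no <- read_noesy(f, "short")
  expect_equal(no$c1[1], 10.1)
  expect_equal(no$c2[1], 24.5)
  expect_equal(no$h2[1], 0.83)
  expect_true(all(no$mixing_class == "short"))
  expect_equal(no$noe_id, 1:2)

  f4 <- write_lines_tmp("13.0 0.6 24.5 0.85")
  no4 <- read_noesy(f4, "long")
  expect_equal(no4$h1, 0.6)
  expect_equal(no4$c2, 24.5)

  fx <- write_lines_tmp("c1 c2 h2", "10.1 aa 0.83")
  expect_error(read_noesy(fx, "long"), "line 2")

  fe <- write_lines_tmp("# nothing")
  expect_warning(no0 <- read_noesy(fe, "long"), "empty")
  expect_equal(nrow(no0), 0)

  # direct-dimension-first files are swapped on input
  fr <- write_lines_tmp("24.5 10.1 0.83")
  nr <- read_noesy(fr, "long", indirect_first = FALSE)
  expect_equal(nr$c1, 10.1)
  expect_equal(nr$c2, 24.5)
})

test_that("2D list writing round-trips every field exactly", {
  ins <- simulate_instance(12, seed = 5)
  f <- tempfile()
  write_hmqc(ins$peaks2d, f)
  back <- read_hmqc(f)
  expect_equal(back$peak_id, ins$peaks2d$peak_id)
  expect_equal(back$c_shift, ins$peaks2d$c_shift, tolerance = 1e-5)
  expect_equal(back$allowed_types, ins$peaks2d$allowed_types)
  expect_equal(back$geminal_partner, ins$peaks2d$geminal_partner)
  expect_equal(back$stereo, ins$peaks2d$stereo)
  f2 <- tempfile()
  write_noesy(ins$noesy_long, f2)
  back2 <- read_noesy(f2, "long")
  expect_equal(back2$c1, ins$noesy_long$c1, tolerance = 1e-5)
})
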