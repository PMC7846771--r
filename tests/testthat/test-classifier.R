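# Chemical-shift residue-type classification.

test_that("minimal cumulative-frequency rule does the arithmetic", {
  # a hand-built table: one well-separated bin per scenario
  params <- data.frame(
    res_type = c("ILE", "LEU", "VAL"), atom = c("CD1", "CD1", "CG1"),
    c_mean = c(13, 24.6, 24.0), c_sd = c(0.5, 1.2, 1.2),
    h_mean = c(0.7, 0.8, 0.8), h_sd = c(0.1, 0.2, 0.2),
    weight = c(1, 1, 1))
  tab <- build_shift_table(params)
  # far inside the isolated Ile region: a singleton
  expect_equal(classify_residue_type(13, 0.7, tab), "I")
  # deep in the Leu/Val overlap: both types, never Ile
  got <- classify_residue_type(24.3, 0.8, tab)
  expect_true(got %in% c("LV", "VL"))
  # outside coverage: "any" with a warning
  expect_warning(out <- classify_residue_type(50, 3, tab), "coverage")
  expect_equal(out, "any")
})

test_that("lowering the threshold never enlarges the returned set", {
  tab <- build_shift_table()
  set.seed(41)
  draws <- sample_methyl_shifts(200, tab)
  hi <- classify_residue_type(draws$c_shift, draws$h_shift, tab,
                              threshold = 0.99)
  lo <- classify_residue_type(draws$c_shift, draws$h_shift, tab,
                              threshold = 0.90)
  for (k in seq_along(hi)) {
    if (hi[k] == "any" || lo[k] == "any") next
    expect_true(all(strsplit(lo[k], "")[[1]] %in% strsplit(hi[k], "")[[1]]))
  }
})

test_that("self-consistency: the true type is contained in >= 99% of draws", {
  tab <- build_shift_table()
  set.seed(42)
  n <- 1e5
  draws <- sample_methyl_shifts(n, tab)
  # a handful of extreme draws fall outside the table's grid and warn;
  # they classify as "any", which counts as containment
  pred <- suppressWarnings(
    classify_residue_type(draws$c_shift, draws$h_shift, tab))
  truth <- methylsat:::RES1[draws$res_type]
  hit <- pred == "any" |
    mapply(grepl, truth, pred, MoreArgs = list(fixed = TRUE))
  expect_gte(mean(hit), 0.99)
})

test_that("the pipeline can classify unannotated peaks", {
  ins <- simulate_instance(10, seed = 43, annotate_types = FALSE,
                           annotate_geminal = FALSE)
  cfg <- run_config(classify = TRUE)
  ri <- methylsat:::resolve_inputs(cfg, list(
    graph = ins$structure$graph, peaks2d = ins$peaks2d,
    noesy_short = ins$noesy_short, noesy_long = ins$noesy_long))
  expect_true(any(ri$peaks2d$allowed_types != "any"))
  # the classified types still admit the planted assignment
  for (p in seq_len(nrow(ri$peaks2d))) {
    tp <- ri$peaks2d$allowed_types[p]
    if (tp == "any") next
    truth_letter <- substr(ins$truth$mapping[[as.character(
      ri$peaks2d$peak_id[p])]], 1, 1)
    expect_true(grepl(truth_letter, tp, fixed = TRUE))
  }
})
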