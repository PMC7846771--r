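# The CNF encoding, the CDCL solver and the support-set enumeration.

# build an instance directly from objects (no file IO)
encode_from <- function(ins, cfg = run_config()) {
  net <- methylsat:::derive_network(cfg, ins$peaks2d, ins$noesy_short,
                                    ins$noesy_long)
  encode_assignment(ins$structure$graph, ins$peaks2d, net$clustered,
                    net$cluster, net$sym)
}

test_that("the solver decides small formulas correctly under assumptions", {
  # pigeonhole: 3 pigeons, 2 holes is unsatisfiable
  p <- methylsat:::.sat_new(6L)
  hole <- function(pg, h) (pg - 1L) * 2L + h
  for (pg in 1:3) methylsat:::.sat_add_clause(p, c(hole(pg, 1L), hole(pg, 2L)))
  for (h in 1:2) for (p1 in 1:2) for (p2 in (p1 + 1):3)
    methylsat:::.sat_add_clause(p, c(-hole(p1, h), -hole(p2, h)))
  expect_equal(methylsat:::.sat_solve(p, integer(0), -1)$status, "unsat")

  # satisfiable formula; model is verified by clause re-evaluation in C++
  q <- methylsat:::.sat_new(4L)
  cls <- list(c(1L, 2L), c(-1L, 3L), c(-2L, -3L), c(2L, 4L))
  for (cl in cls) methylsat:::.sat_add_clause(q, cl)
  r <- methylsat:::.sat_solve(q, integer(0), -1)
  expect_equal(r$status, "sat")
  lit_true <- function(l) (r$model[abs(l)] == 1) == (l > 0)
  for (cl in cls) expect_true(any(vapply(cl, lit_true, logical(1))))
  # assumptions flip the outcome without touching the formula
  expect_equal(methylsat:::.sat_solve(q, c(1L, 2L), -1)$status, "unsat")
  expect_equal(methylsat:::.sat_solve(q, c(1L), -1)$status, "sat")
})

test_that("two peaks forced onto one methyl are unsatisfiable", {
  ins <- simulate_instance(6, seed = 61, annotate_geminal = FALSE,
                           connectivity = c(0.5, 4.2))
  # force two peaks to the same methyl via fixed assignments
  m <- ins$truth$mapping[[1]]
  ins$peaks2d$fixed_assignment[1] <- m
  ins$peaks2d$fixed_assignment[2] <- m
  ins$peaks2d$allowed_types[1:2] <- "any"
  inst <- encode_from(ins)
  eng <- sat_engine(inst)
  expect_equal(solve_once(eng)$status, "unsat")
})

test_that("a data graph that does not fit the structure graph is refuted", {
  # take a valid instance but replace the structure with a fresh fold of
  # the same composition: the NOE network should not embed
  ins <- simulate_instance(15, seed = 62)
  other <- synth_structure(15, seed = 9901,
                           residue_types = strsplit(ins$structure$sequence,
                                                    "")[[1]])
  cfg <- run_config()
  res <- run_assignment(cfg, list(graph = other$graph, peaks2d = ins$peaks2d,
                                  noesy_short = ins$noesy_short,
                                  noesy_long = ins$noesy_long))
  expect_equal(res$status, "unsat")
  expect_true(length(res$diagnostics) > 0)
})

test_that("fixed assignments become unit clauses and empty domains error", {
  ins <- simulate_instance(8, seed = 63, connectivity = c(0.5, 4.2))
  pid <- names(ins$truth$mapping)[3]
  ins$peaks2d$fixed_assignment[match(as.integer(pid),
                                     ins$peaks2d$peak_id)] <-
    ins$truth$mapping[[pid]]
  inst <- encode_from(ins)
  eng <- sat_engine(inst)
  s <- enumerate_support_sets(eng)
  expect_equal(s$supports[[pid]], unname(ins$truth$mapping[[pid]]))

  ins$peaks2d$allowed_types[1] <- "M"  # no Met in an ILV instance
  expect_error(encode_from(ins), "exclude")
})

test_that("support sets equal brute-force enumeration on random toy instances", {
  set.seed(64)
  cfg <- run_config()
  n_checked <- 0
  for (seed in 1:30) {
    n <- sample(4:6, 1)
    ins <- simulate_instance(
      n, seed = 6400 + seed, connectivity = c(0.5, 4.2),
      overlap_rate = sample(c(0, 0.2, 0.4), 1),
      jitter_ppm = sample(c(0, 0.02, 0.05), 1),
      annotate_types = sample(c(TRUE, FALSE), 1),
      annotate_geminal = sample(c(TRUE, FALSE), 1))
    # occasionally drop a 2D peak (missing resonance)
    if (runif(1) < 0.3) {
      drop <- sample(nrow(ins$peaks2d), 1)
      gp <- ins$peaks2d$geminal_partner[drop]
      if (!is.na(gp))
        ins$peaks2d$geminal_partner[match(gp, ins$peaks2d$peak_id)] <-
          NA_integer_
      ins$peaks2d <- ins$peaks2d[-drop, ]
    }
    if (!oracle_tractable(ins$peaks2d, ins$noesy_short, ins$noesy_long,
                          cfg)) next
    got <- package_supports(ins$structure$graph, ins$peaks2d,
                            ins$noesy_short, ins$noesy_long, cfg)
    want <- oracle_pipeline(ins$structure$graph, ins$peaks2d,
                            ins$noesy_short, ins$noesy_long, cfg)
    expect_equal(got$status, want$status, info = paste("seed", seed))
    if (got$status == "sat") {
      expect_equal(got$supports[names(want$supports)], want$supports,
                   info = paste("seed", seed))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("supports are order-invariant and exclusivity holds", {
  ins <- simulate_instance(12, seed = 65, overlap_rate = 0.15)
  inst <- encode_from(ins)
  s1 <- enumerate_support_sets(sat_engine(inst))
  # re-encode with permuted peak rows: same sets must come out
  perm <- sample(nrow(ins$peaks2d))
  ins2 <- ins
  ins2$peaks2d <- ins$peaks2d[perm, ]
  s2 <- enumerate_support_sets(sat_engine(encode_from(ins2)))
  for (pid in names(s1$supports))
    expect_setequal(s1$supports[[pid]], s2$supports[[pid]])
  # uniquely assigned methyls never appear in other peaks' supports
  uni <- unlist(s1$supports[lengths(s1$supports) == 1])
  for (pid in names(s1$supports)) {
    s <- s1$supports[[pid]]
    if (length(s) > 1) expect_length(intersect(s, uni), 0)
  }
})

test_that("every reported option extends to a full model (soundness)", {
  ins <- simulate_instance(10, seed = 66, overlap_rate = 0.2)
  inst <- encode_from(ins)
  eng <- sat_engine(inst)
  s <- enumerate_support_sets(eng)
  expect_equal(s$status, "sat")
  for (i in seq_along(inst$x)) {
    pid <- as.character(inst$peaks2d$peak_id[i])
    for (m in s$supports[[pid]]) {
      r <- methylsat:::engine_solve(eng, inst$x[[i]][[m]])
      expect_equal(r$status, "sat")
    }
  }
})

test_that("DIMACS export is well formed", {
  ins <- simulate_instance(6, seed = 67, connectivity = c(0.5, 4.2))
  inst <- encode_from(ins)
  f <- tempfile()
  write_dimacs(inst, f)
  lines <- readLines(f)
  hdr <- strsplit(lines[1], " ")[[1]]
  expect_equal(hdr[1:2], c("p", "cnf"))
  expect_equal(as.integer(hdr[4]), length(lines) - 1)
  lits <- unlist(lapply(lines[-1], function(x)
    as.integer(strsplit(x, " ")[[1]])))
  expect_true(all(abs(lits) <= as.integer(hdr[3])))
})
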