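# The synthetic benchmark generator.

test_that("two methyls at 5 Angstrom give one short edge", {
  carb <- rbind(c(0, 0, 0), c(5, 0, 0))
  sim <- synth_structure(2, residue_types = c("I", "I"),
                         carbon_positions = carb, seed = 1)
  expect_equal(nrow(sim$graph$edges), 1)
  expect_equal(sim$graph$edges$class, "short")
})

test_that("generated clouds have protein-like connectivity and geminal pairs", {
  sim <- synth_structure(50, seed = 51)
  g <- sim$graph
  expect_equal(nrow(g$methyls), 50)
  expect_true(all(c("short", "long", "geminal") %in% g$edges$class))
  expect_gte(degree_connectivity(g), 4.2)
  # geminal effective distances are physically short
  gem <- g$edges[g$edges$class == "geminal", ]
  expect_true(all(gem$distance < 4))
  # same seed reproduces the instance bit-identically
  sim2 <- synth_structure(50, seed = 51)
  expect_identical(sim$graph$edges, sim2$graph$edges)
  expect_identical(sim$methyls$protons, sim2$methyls$protons)
  expect_error(synth_structure(30, density = 0.5, min_sep = 10, seed = 1),
               "packing")
})

test_that("data-graph sampling hits the connectivity target and H stays in G", {
  sim <- synth_structure(60, seed = 52)
  h <- sample_data_graph(sim$graph, target = c(3.5, 4.2), seed = 52)
  conn <- degree_connectivity(nrow(h$edges), nrow(sim$graph$methyls))
  expect_gte(conn, 3.5)
  expect_lte(conn, 4.2)
  expect_true(all(paste(h$edges$a, h$edges$b) %in%
                  paste(sim$graph$edges$a, sim$graph$edges$b)))
  # a target equal to G's own connectivity keeps H = G
  cg <- degree_connectivity(sim$graph)
  h2 <- sample_data_graph(sim$graph, target = c(cg - 0.01, cg + 0.01))
  expect_equal(nrow(h2$edges), nrow(sim$graph$edges))
  # unreachable target errors
  expect_error(sample_data_graph(sim$graph, target = c(90, 95)), "below")
})

test_that("peak lists carry the planted truth within tolerances", {
  ins <- simulate_instance(25, seed = 53, overlap_rate = 0.1,
                           jitter_ppm = 0.02)
  truth <- ins$truth
  # every 2D peak's shift equals its methyl's planted shift
  sh <- truth$shifts
  for (p in seq_len(nrow(ins$peaks2d))) {
    m <- truth$mapping[[as.character(ins$peaks2d$peak_id[p])]]
    expect_equal(ins$peaks2d$c_shift[p], sh$c_shift[match(m, sh$methyl)])
  }
  # every NOE is within clustering tolerance of its planted 2D peak
  nt <- truth$noe_truth$long
  planted_rows <- seq_len(nrow(nt))
  for (k in head(planted_rows, 50)) {
    m_to <- nt$methyl_to[k]
    expect_lt(abs(ins$noesy_long$c2[k] - sh$c_shift[match(m_to, sh$methyl)]),
              0.15)
    expect_lt(abs(ins$noesy_long$h2[k] - sh$h_shift[match(m_to, sh$methyl)]),
              0.02)
  }
  # short list holds short-range and geminal edges only
  short_cls <- ins$h$edges$class[match(
    paste(pmin(truth$noe_truth$short$methyl_from,
               truth$noe_truth$short$methyl_to),
          pmax(truth$noe_truth$short$methyl_from,
               truth$noe_truth$short$methyl_to)),
    paste(pmin(ins$h$edges$a, ins$h$edges$b),
          pmax(ins$h$edges$a, ins$h$edges$b)))]
  expect_true(all(short_cls %in% c("short", "geminal")))
  # same seed, same files
  ins2 <- simulate_instance(25, seed = 53, overlap_rate = 0.1,
                            jitter_ppm = 0.02)
  expect_identical(ins$peaks2d, ins2$peaks2d)
  expect_identical(ins$noesy_long, ins2$noesy_long)
})

test_that("forced overlap creates clustering ambiguity", {
  ins <- simulate_instance(30, seed = 54, overlap_rate = 0.3)
  cfg <- run_config()
  net <- methylsat:::derive_network(cfg, ins$peaks2d, ins$noesy_short,
                                    ins$noesy_long)
  expect_gt(sum(lengths(net$cluster$candidates) > 1), 0)
})

test_that("noiseless small instance is recovered exactly with simple components", {
  ins <- simulate_instance(12, seed = 55, overlap_rate = 0, jitter_ppm = 0)
  cfg <- run_config()
  net <- methylsat:::derive_network(cfg, ins$peaks2d, ins$noesy_short,
                                    ins$noesy_long)
  expect_true(all(net$sym$components$class == "simple"))
  res <- run_assignment(cfg, list(graph = ins$structure$graph,
                                  peaks2d = ins$peaks2d,
                                  noesy_short = ins$noesy_short,
                                  noesy_long = ins$noesy_long))
  expect_equal(res$status, "assigned")
  for (pid in names(ins$truth$mapping))
    expect_true(ins$truth$mapping[[pid]] %in% res$supports[[pid]])
})
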