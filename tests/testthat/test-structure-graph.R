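# Structure graph construction: edge classes, thresholds, ensembles,
# oligomer collapsing.

test_that("geminal edges are categorical, distance edges follow thresholds", {
  # Ile pair at ~5 A, Ile pair at ~9 A, Ile pair at ~11 A (carbon-carbon);
  # one Leu contributes a geminal pair
  carb <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 40, 0), c(9, 40, 0),
                c(0, 80, 0), c(11.5, 80, 0),
                c(0, 120, 0), c(2.55, 120, 0))
  ms <- toy_methyl_set(carb, c("I", "I", "I", "I", "I", "I", "L"))
  g <- build_structure_graph(ms, short_radius = 6, long_radius = 10)
  gem <- g$edges[g$edges$class == "geminal", ]
  expect_equal(nrow(gem), 1)
  expect_setequal(c(gem$a, gem$b), c("L7CD1", "L7CD2"))
  key <- function(a, b) g$edges$class[(g$edges$a == a & g$edges$b == b) |
                                      (g$edges$a == b & g$edges$b == a)]
  expect_equal(key("I1CD1", "I2CD1"), "short")
  expect_equal(key("I3CD1", "I4CD1"), "long")
  expect_length(key("I5CD1", "I6CD1"), 0)
})

test_that("edge set equals an exhaustive O(n^2) scan with threshold classing", {
  sim <- synth_structure(30, seed = 31)
  g <- sim$graph
  ms <- sim$methyls
  n <- nrow(ms$table)
  expected <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- effective_distance(ms$protons[1, i, , ], ms$protons[1, j, , ])
    gem <- !is.na(ms$table$geminal_id[i]) &&
      ms$table$geminal_id[i] == ms$table$id[j]
    if (!gem && d > g$long_radius) next
    cls <- if (gem) "geminal" else if (d <= g$short_radius) "short" else "long"
    expected[[length(expected) + 1]] <-
      data.frame(a = ms$table$id[i], b = ms$table$id[j], class = cls,
                 distance = d)
  }
  expected <- do.call(rbind, expected)
  got <- g$edges[order(g$edges$a, g$edges$b), ]
  expected <- expected[order(expected$a, expected$b), ]
  expect_equal(got$a, expected$a)
  expect_equal(got$b, expected$b)
  expect_equal(got$class, expected$class)
  expect_equal(got$distance, expected$distance, tolerance = 1e-9)
})

test_that("radius validation and edge-count monotonicity hold", {
  sim <- synth_structure(20, seed = 32)
  ms <- sim$methyls
  expect_error(build_structure_graph(ms, short_radius = 8, long_radius = 7),
               "exceed")
  expect_error(build_structure_graph(ms, short_radius = 4, long_radius = 10),
               "6-8")
  g10 <- build_structure_graph(ms, short_radius = 7, long_radius = 10)
  g12 <- build_structure_graph(ms, short_radius = 7, long_radius = 12)
  k10 <- paste(g10$edges$a, g10$edges$b)
  k12 <- paste(g12$edges$a, g12$edges$b)
  expect_true(all(k10 %in% k12))
})

test_that("ensemble minima only add or shorten edges", {
  p1 <- write_tiny_pdb(n_models = 1)
  p3 <- write_tiny_pdb(n_models = 3, shift = c(-1.5, 0, 0))
  g1 <- build_structure_graph(extract_methyls(read_structure(p1), "ILV", "LVI"),
                              force = TRUE)
  g3 <- build_structure_graph(extract_methyls(read_structure(p3), "ILV", "LVI"),
                              force = TRUE)
  expect_true(all(g3$distance_matrix <= g1$distance_matrix + 1e-9))
  expect_true(all(paste(g1$edges$a, g1$edges$b) %in%
                  paste(g3$edges$a, g3$edges$b)))
})

test_that("oligomer mode collapses chains and takes the interface minimum", {
  p <- write_tiny_pdb()
  s <- read_structure(p)
  # duplicate the structure as a second chain shifted by 4 A
  atoms2 <- s$atoms
  atoms2$chain <- "B"
  coords <- array(NA_real_, c(1, 2 * nrow(s$atoms), 3))
  coords[1, seq_len(nrow(s$atoms)), ] <- s$coords[1, , ]
  coords[1, nrow(s$atoms) + seq_len(nrow(s$atoms)), ] <-
    s$coords[1, , ] + rep(c(0, 0, 4), each = nrow(s$atoms))
  dimer <- methylsat:::new_structure_models(rbind(s$atoms, atoms2), coords)
  ms <- extract_methyls(dimer, "ILV", "LVI")
  expect_equal(nrow(ms$table), 10)
  g <- build_structure_graph(ms, oligomer_chains = c("A", "B"))
  expect_equal(nrow(g$methyls), 5)
  # collapsed distance is the minimum over chain pairings, so it can only
  # be smaller than the within-chain distance
  gA <- build_structure_graph(extract_methyls(s, "ILV", "LVI"))
  expect_true(all(g$distance_matrix <= gA$distance_matrix + 1e-9))
})

test_that("degree connectivity follows its definition", {
  expect_equal(degree_connectivity(7, 4), 3.5)
  sim <- synth_structure(15, seed = 33)
  expect_equal(degree_connectivity(sim$graph),
               2 * nrow(sim$graph$edges) / nrow(sim$graph$methyls))
})

test_that("edge-list export round-trips through a TSV", {
  sim <- synth_structure(10, seed = 34)
  f <- tempfile()
  write_structure_graph(sim$graph, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(sim$graph$edges))
  expect_named(tab, c("methyl_a", "methyl_b", "distance_A", "class"))
})
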