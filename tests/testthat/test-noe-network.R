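# NOE network derivation: diagonal elimination, clustering, symmetrization
# components and maximum-matching enumeration.

mk_noes <- function(m, mixing = "long") {
  structure(data.frame(noe_id = seq_len(nrow(m)), c1 = m[, 1], c2 = m[, 2],
                       h2 = m[, 3], h1 = NA_real_, mixing_class = mixing,
                       stringsAsFactors = FALSE),
            class = c("noe_list", "data.frame"))
}

mk_peaks <- function(c, h) {
  validate_peaks2d(data.frame(
    peak_id = seq_along(c), c_shift = c, h_shift = h, allowed_types = "any",
    stereo = "unknown", geminal_partner = NA_integer_,
    fixed_assignment = NA_character_, stringsAsFactors = FALSE))
}

test_that("diagonal elimination uses a strict tolerance and labels sides", {
  no <- mk_noes(rbind(c(24.50, 24.52, 0.8), c(18.0, 24.5, 0.8),
                      c(26.0, 24.5, 0.8)))
  de <- eliminate_diagonal(no, 0.15)
  expect_equal(de$eliminated, 1L)
  expect_equal(de$retained$diagonal_side, c("lower", "upper"))
  # zero tolerance keeps everything
  expect_length(eliminate_diagonal(no, 0)$eliminated, 0)
})

test_that("clustering matches the brute-force double loop", {
  set.seed(21)
  pk <- mk_peaks(runif(20, 10, 26), runif(20, 0.4, 1.2))
  no <- mk_noes(cbind(runif(100, 10, 26), runif(100, 10, 26),
                      runif(100, 0.4, 1.2)))
  cl <- cluster_noes(no, pk, 0.15, 0.02)
  for (k in seq_len(nrow(no))) {
    want <- pk$peak_id[abs(no$c2[k] - pk$c_shift) < 0.15 &
                       abs(no$h2[k] - pk$h_shift) < 0.02]
    if (length(want) == 0) {
      expect_true(no$noe_id[k] %in% cl$unclustered)
    } else {
      expect_setequal(cl$candidates[[as.character(no$noe_id[k])]], want)
    }
  }
  # candidate sets are monotone in the tolerances
  cl_small <- cluster_noes(no, pk, 0.05, 0.01)
  for (id in names(cl_small$candidates))
    expect_true(all(cl_small$candidates[[id]] %in% cl$candidates[[id]]))
})

test_that("overlapping peaks produce ambiguous candidate sets", {
  pk <- mk_peaks(c(24.50, 24.55), c(0.800, 0.805))
  no <- mk_noes(rbind(c(10, 24.525, 0.8025)))
  cl <- cluster_noes(no, pk, 0.15, 0.02)
  expect_setequal(cl$candidates[["1"]], c(1, 2))
})

test_that("symmetrization graph is bipartite and matches a brute-force scan", {
  set.seed(22)
  # random NOEs clustered around a few carbon shifts so mirrors are common
  cshifts <- runif(8, 12, 26)
  pick <- function(n) sample(cshifts, n, replace = TRUE)
  a <- pick(30); b <- pick(30)
  no <- mk_noes(cbind(a + rnorm(30, 0, 0.05), b + rnorm(30, 0, 0.05),
                      runif(30, 0.5, 1)))
  de <- eliminate_diagonal(no, 0.15)
  ret <- de$retained
  sym <- build_symmetrization_graph(ret, 0.15)
  # brute force edges
  want <- list()
  for (i in seq_len(nrow(ret))) for (j in seq_len(nrow(ret))) {
    if (ret$diagonal_side[i] != "upper" || ret$diagonal_side[j] != "lower")
      next
    if (abs(ret$c2[i] - ret$c1[j]) < 0.15 && abs(ret$c1[i] - ret$c2[j]) < 0.15)
      want[[length(want) + 1]] <- c(ret$noe_id[i], ret$noe_id[j])
  }
  want <- do.call(rbind, want)
  expect_equal(nrow(sym$edges), NROW(want))
  if (NROW(want))
    expect_setequal(paste(sym$edges$upper, sym$edges$lower),
                    paste(want[, 1], want[, 2]))
  # strict bipartiteness: upper column only ever holds upper-side peaks
  ups <- ret$noe_id[ret$diagonal_side == "upper"]
  expect_true(all(sym$edges$upper %in% ups))
  expect_false(any(sym$edges$lower %in% ups))
  # components agree with an independent union-find (igraph)
  if (nrow(sym$edges)) {
    g <- igraph::graph_from_edgelist(
      cbind(paste0("u", sym$edges$upper), paste0("l", sym$edges$lower)),
      directed = FALSE)
    expect_equal(nrow(sym$components), igraph::components(g)$no)
  }
  # component classes: simple iff <= 2 edges
  expect_equal(sym$components$class == "simple", sym$components$n_edges <= 2)
})

test_that("shrinking the symmetrization tolerance never adds edges", {
  set.seed(23)
  no <- mk_noes(cbind(runif(40, 12, 26), runif(40, 12, 26), runif(40, 0.5, 1)))
  ret <- eliminate_diagonal(no, 0.15)$retained
  wide <- build_symmetrization_graph(ret, 0.3)
  narrow <- build_symmetrization_graph(ret, 0.1)
  expect_true(all(paste(narrow$edges$upper, narrow$edges$lower) %in%
                  paste(wide$edges$upper, wide$edges$lower)))
})

test_that("exact mirrors form a size-2 simple component", {
  no <- mk_noes(rbind(c(18.0, 24.5, 0.8), c(24.5, 18.0, 0.6)))
  ret <- eliminate_diagonal(no, 0.15)$retained
  sym <- build_symmetrization_graph(ret, 0.15)
  expect_equal(nrow(sym$edges), 1)
  expect_equal(sym$components$class, "simple")
  expect_equal(sym$components$n_nodes, 2L)
})

test_that("maximum matchings are exhaustive and maximum (subset oracle)", {
  brute_mm <- function(edges) {
    ne <- nrow(edges)
    best <- 0
    keep <- list()
    for (sz in seq_len(ne)) for (pick in combn(ne, sz, simplify = FALSE)) {
      sub <- edges[pick, , drop = FALSE]
      if (anyDuplicated(sub$upper) || anyDuplicated(sub$lower)) next
      if (sz > best) { best <- sz; keep <- list() }
      if (sz == best) keep[[length(keep) + 1]] <- sub
    }
    keep
  }
  canon <- function(m) paste(sort(paste(m$upper, m$lower)), collapse = ";")
  # complete bipartite 2x2: two maximum matchings
  e22 <- data.frame(upper = c(1, 1, 2, 2), lower = c(10, 11, 10, 11))
  mm <- enumerate_maximum_matchings(e22)
  expect_length(mm, 2)
  expect_true(all(vapply(mm, nrow, integer(1)) == 2))
  # path u1-l1-u2: two maximum matchings of size 1
  ep <- data.frame(upper = c(1, 2), lower = c(10, 10))
  mmp <- enumerate_maximum_matchings(ep)
  expect_setequal(vapply(mmp, canon, character(1)), c("1 10", "2 10"))
  # random bipartite graphs vs subset enumeration
  set.seed(24)
  for (rep in 1:25) {
    nu <- sample(2:4, 1); nl <- sample(2:4, 1)
    all_e <- expand.grid(upper = seq_len(nu), lower = 10 + seq_len(nl))
    es <- all_e[runif(nrow(all_e)) < 0.5, , drop = FALSE]
    if (nrow(es) == 0) next
    got <- enumerate_maximum_matchings(es)
    want <- brute_mm(es)
    expect_setequal(vapply(got, canon, character(1)),
                    vapply(want, canon, character(1)))
  }
  # the cap leaves a warning and a flag
  big <- expand.grid(upper = 1:6, lower = 10 + 1:6)
  expect_warning(capped <- enumerate_maximum_matchings(big, cap = 5),
                 "cap")
  expect_true(attr(capped, "capped"))
})
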