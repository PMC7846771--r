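# The structure graph G: labeled methyls as nodes, edges for every pair
# whose ensemble-minimum effective distance falls within the NOE-observable
# radii, classed as geminal / short-range / long-range.

#' Build the methyl structure graph
#'
#' Edges connect every methyl pair whose ensemble-minimum effective distance
#' Delta is at most `long_radius`. Classes: `geminal` for the two methyls of
#' one Leu or Val residue (always present, regardless of Delta), `short` for
#' Delta <= `short_radius`, `long` for `short_radius` < Delta <=
#' `long_radius`. Recommended radii are 6-8 Angstrom (short, the maximum
#' distance observable at ~50 ms NOESY mixing) and 10-12 Angstrom (long,
#' ~300 ms); values outside these ranges require `force = TRUE`.
#'
#' In oligomer mode, methyls of the declared identical chains are collapsed
#' to their unique (residue number, atom) identity and Delta is the minimum
#' over all intra- and inter-chain pairings, so that subunit-interface NOEs
#' are representable.
#'
#' @param methyls a `methyl_set` from [extract_methyls()].
#' @param short_radius,long_radius distance thresholds in Angstrom.
#' @param oligomer_chains character vector of chain identifiers to collapse
#'   as identical subunits, or `NULL` (default: all chains distinct).
#' @param force bypass the recommended-range check on the radii.
#' @return object of class `structure_graph`: list with `methyls` (node
#'   table), `edges` (data.frame: a, b, distance, class), and the radii.
#' @export
build_structure_graph <- function(methyls, short_radius = 8, long_radius = 10,
                                  oligomer_chains = NULL, force = FALSE) {
  stopifnot(inherits(methyls, "methyl_set"))
  if (long_radius <= short_radius)
    stop("long_radius must exceed short_radius")
  if (!force && (short_radius < 6 || short_radius > 8))
    stop("short_radius should be within 6-8 Angstrom (use force = TRUE to override)")
  if (!force && (long_radius < 10 || long_radius > 12))
    stop("long_radius should be within 10-12 Angstrom (use force = TRUE to override)")

  tab <- methyls$table
  pr <- methyls$protons
  n_models <- dim(pr)[1]

  # full inter-proton distance matrix per model, aggregated per methyl pair:
  # Delta = min over models of ((1/9) sum d^-6)^(-1/6)
  n <- nrow(tab)
  dmat <- matrix(Inf, n, n)
  for (s in seq_len(n_models)) {
    # rows ordered: methyl 1 protons 1-3, methyl 2 protons 1-3, ...
    flat <- matrix(NA_real_, 3 * n, 3)
    for (i in seq_len(n)) flat[(3 * i - 2):(3 * i), ] <- pr[s, i, , ]
    pd2 <- as.matrix(stats::dist(flat))^2
    inv6 <- (pd2 + diag(1e-12, 3 * n))^-3
    agg <- matrix(0, n, n)
    for (a in 1:3) for (b in 1:3)
      agg <- agg + inv6[seq(a, 3 * n, by = 3), seq(b, 3 * n, by = 3)]
    ds <- (agg / 9)^(-1 / 6)
    dmat <- pmin(dmat, ds)
  }
  diag(dmat) <- Inf

  if (!is.null(oligomer_chains)) {
    grp_key <- ifelse(tab$chain %in% oligomer_chains,
                      paste0("*", tab$resno, ".", tab$atom),
                      paste0(tab$chain, ".", tab$resno, ".", tab$atom))
  } else {
    grp_key <- paste0(tab$chain, ".", tab$resno, ".", tab$atom)
  }
  groups <- split(seq_len(n), grp_key)
  reps <- vapply(groups, `[`, integer(1), 1)
  # order groups by first occurrence so output is stable
  reps <- sort(reps)
  groups <- lapply(reps, function(r) groups[[grp_key[r]]])
  m <- length(reps)
  node_tab <- tab[reps, , drop = FALSE]
  multi <- length(unique(node_tab$chain)) > 1 && is.null(oligomer_chains)
  node_tab$id <- methyl_label(node_tab$res_type, node_tab$resno, node_tab$atom,
                              node_tab$chain, multi)
  # refresh geminal ids under possibly collapsed labels
  node_tab$geminal_id <- NA_character_
  lv <- node_tab$res_type %in% c("LEU", "VAL")
  for (i in which(lv)) {
    sib <- which(lv & node_tab$chain == node_tab$chain[i] &
                 node_tab$resno == node_tab$resno[i] &
                 node_tab$atom != node_tab$atom[i])
    if (length(sib) == 1) node_tab$geminal_id[i] <- node_tab$id[sib]
  }
  rownames(node_tab) <- NULL

  gdmat <- matrix(Inf, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    gdmat[i, j] <- gdmat[j, i] <- min(dmat[groups[[i]], groups[[j]]])
  }

  edges <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    gem <- !is.na(node_tab$geminal_id[i]) &&
      node_tab$geminal_id[i] == node_tab$id[j]
    d <- gdmat[i, j]
    if (!gem && d > long_radius) next
    cls <- if (gem) "geminal" else if (d <= short_radius) "short" else "long"
    edges[[length(edges) + 1]] <-
      data.frame(a = node_tab$id[i], b = node_tab$id[j],
                 distance = d, class = cls, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0),
               distance = numeric(0), class = character(0))

  structure(list(methyls = node_tab, edges = edges,
                 short_radius = short_radius, long_radius = long_radius,
                 distance_matrix = gdmat),
            class = "structure_graph")
}

#' Reclassify the edges of a structure graph under new radii
#'
#' Reuses the stored ensemble-minimum distances, so the (expensive) distance
#' computation is done once when scanning radii.
#'
#' @param graph a `structure_graph`.
#' @inheritParams build_structure_graph
#' @return a `structure_graph` with the same nodes and updated edges.
#' @export
reclassify_structure_graph <- function(graph, short_radius, long_radius,
                                       force = TRUE) {
  stopifnot(inherits(graph, "structure_graph"))
  if (long_radius <= short_radius) stop("long_radius must exceed short_radius")
  tab <- graph$methyls
  gd <- graph$distance_matrix
  m <- nrow(tab)
  edges <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    gem <- !is.na(tab$geminal_id[i]) && tab$geminal_id[i] == tab$id[j]
    d <- gd[i, j]
    if (!gem && d > long_radius) next
    cls <- if (gem) "geminal" else if (d <= short_radius) "short" else "long"
    edges[[length(edges) + 1]] <-
      data.frame(a = tab$id[i], b = tab$id[j], distance = d, class = cls,
                 stringsAsFactors = FALSE)
  }
  graph$edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0),
               distance = numeric(0), class = character(0))
  graph$short_radius <- short_radius
  graph$long_radius <- long_radius
  graph
}

#' Degree connectivity of a graph
#'
#' The sparsity measure `2 * number of edges / number of nodes`. An NOE
#' network with degree connectivity c corresponds to c/2 experimentally
#' observed NOE peaks per methyl (each edge is observed as an
#' upper/lower-diagonal cross-peak pair).
#'
#' @param n_edges,n_nodes edge and node counts, or a `structure_graph` as
#'   first argument.
#' @return degree connectivity (dimensionless).
#' @export
degree_connectivity <- function(n_edges, n_nodes) {
  if (inherits(n_edges, "structure_graph")) {
    g <- n_edges
    return(2 * nrow(g$edges) / nrow(g$methyls))
  }
  2 * n_edges / n_nodes
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("<structure_graph> %d methyls, %d edges (radii %.1f/%.1f A)\n",
              nrow(x$methyls), nrow(x$edges), x$short_radius, x$long_radius))
  if (nrow(x$edges)) print(table(x$edges$class))
  cat(sprintf("degree connectivity: %.2f\n", degree_connectivity(x)))
  invisible(x)
}

#' Export a structure graph as a tab-separated edge list
#'
#' Columns: methyl_a, methyl_b, distance_A (reported to 0.1 Angstrom),
#' class.
#'
#' @param graph a `structure_graph`.
#' @param path output file path.
#' @export
write_structure_graph <- function(graph, path) {
  stopifnot(inherits(graph, "structure_graph"))
  out <- graph$edges
  out$distance <- round(out$distance, 1)
  names(out) <- c("methyl_a", "methyl_b", "distance_A", "class")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
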