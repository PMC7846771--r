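# Deriving all candidate data-graph structure from the raw NOE peaks:
# diagonal elimination, clustering to the 2D reference, the bipartite
# upper/lower-diagonal symmetrization graph, component classification and
# exhaustive enumeration of maximum matchings.
#
# All tolerance comparisons are strict ("<"), so a difference exactly equal
# to the tolerance does not match.

#' Eliminate diagonal NOE peaks
#'
#' An NOE whose two 13C coordinates are closer than `diagonal_tol` is a
#' diagonal peak (a methyl seeing itself) and carries no connectivity
#' information. Retained peaks are labeled upper-diagonal (c1 > c2) or
#' lower-diagonal (c2 > c1).
#'
#' @param noes a `noe_list`.
#' @param diagonal_tol 13C tolerance in ppm.
#' @return list with `retained` (noe_list plus `diagonal_side` column) and
#'   `eliminated` (noe ids).
#' @export
eliminate_diagonal <- function(noes, diagonal_tol = 0.15) {
  is_diag <- abs(noes$c1 - noes$c2) < diagonal_tol
  retained <- noes[!is_diag, , drop = FALSE]
  retained$diagonal_side <- ifelse(retained$c1 > retained$c2, "upper", "lower")
  list(retained = retained, eliminated = noes$noe_id[is_diag])
}

#' Cluster NOE cross-peaks to 2D reference peaks
#'
#' A 3D maximum (c1, c2, h2) can project onto a 2D reference maximum (C, H)
#' iff |c2 - C| < `c_tol` and |h2 - H| < `h_tol`. Every 2D peak satisfying
#' both inequalities is a candidate; spectral overlap therefore yields
#' multi-candidate sets, all of which are carried into the constraint
#' system. NOEs with no candidate are eliminated (status "unclustered").
#'
#' @param noes a `noe_list` (typically the retained set after
#'   [eliminate_diagonal()]).
#' @param peaks2d a `peak2d_list`.
#' @param c_tol,h_tol clustering tolerances in ppm (defaults 0.15 for 13C,
#'   0.02 for 1H).
#' @return list with `candidates` (list keyed by as.character(noe_id) of
#'   candidate peak_id vectors) and `unclustered` (noe ids).
#' @export
cluster_noes <- function(noes, peaks2d, c_tol = 0.15, h_tol = 0.02) {
  stopifnot(c_tol > 0, h_tol > 0)
  cands <- lapply(seq_len(nrow(noes)), function(k) {
    hit <- abs(noes$c2[k] - peaks2d$c_shift) < c_tol &
      abs(noes$h2[k] - peaks2d$h_shift) < h_tol
    peaks2d$peak_id[hit]
  })
  names(cands) <- as.character(noes$noe_id)
  empty <- lengths(cands) == 0
  list(candidates = cands[!empty], unclustered = noes$noe_id[empty])
}

#' Build the bipartite symmetrization graph
#'
#' Every true NOE connectivity must appear as an upper-diagonal cross-peak
#' together with its symmetry-related lower-diagonal mirror. Two peaks k
#' (upper) and k' (lower) of the same mixing-time spectrum are potentially
#' symmetric iff |c2 - c1'| < `c_tol_sym` and |c1 - c2'| < `c_tol_sym`;
#' for 4D peak lists the indirect 1H dimension must additionally mirror the
#' direct 1H within `h_tol_sym`. Peaks with no potential mirror are
#' eliminated ("no_symmetric_partner"). Connected components are classified
#' simple (2-3 nodes, at most 2 edges) or complex (>= 3 edges); complex
#' components are later reduced by explicit satisfiability
#' ([reduce_complex_components()]).
#'
#' @param noes retained, clustered NOE table carrying `diagonal_side` and
#'   `mixing_class` columns.
#' @param c_tol_sym 13C symmetrization tolerance in ppm.
#' @param h_tol_sym 1H symmetrization tolerance (4D lists only).
#' @return object of class `sym_graph`: list with `edges` (data.frame:
#'   upper, lower, comp), `components` (data.frame: comp, n_nodes, n_edges,
#'   class), `nodes` (noe ids in the graph) and `isolated` (noe ids).
#' @export
build_symmetrization_graph <- function(noes, c_tol_sym = 0.15,
                                       h_tol_sym = 0.02) {
  edges <- list()
  for (mc in unique(noes$mixing_class)) {
    sub <- noes[noes$mixing_class == mc, , drop = FALSE]
    up <- sub[sub$diagonal_side == "upper", , drop = FALSE]
    lo <- sub[sub$diagonal_side == "lower", , drop = FALSE]
    for (i in seq_len(nrow(up))) for (j in seq_len(nrow(lo))) {
      if (abs(up$c2[i] - lo$c1[j]) < c_tol_sym &&
          abs(up$c1[i] - lo$c2[j]) < c_tol_sym) {
        if (!is.na(up$h1[i]) && !is.na(lo$h1[j]) &&
            !(abs(up$h2[i] - lo$h1[j]) < h_tol_sym &&
              abs(up$h1[i] - lo$h2[j]) < h_tol_sym)) next
        edges[[length(edges) + 1]] <-
          data.frame(upper = up$noe_id[i], lower = lo$noe_id[j],
                     mixing_class = mc, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(upper = integer(0), lower = integer(0),
               mixing_class = character(0))
  classify_sym_graph(edges, noes$noe_id)
}

# recompute components + classes for a given surviving edge set
classify_sym_graph <- function(edges, all_nodes) {
  if (nrow(edges)) {
    vu <- paste0("u", edges$upper)
    vl <- paste0("l", edges$lower)
    g <- igraph::graph_from_edgelist(cbind(vu, vl), directed = FALSE)
    comp <- igraph::components(g)
    vnames <- igraph::V(g)$name
    edge_comp <- comp$membership[vu]
    edges$comp <- as.integer(edge_comp)
    comp_tab <- data.frame(comp = seq_len(comp$no),
                           n_nodes = as.integer(comp$csize))
    ec <- table(factor(edges$comp, levels = comp_tab$comp))
    comp_tab$n_edges <- as.integer(ec)
    comp_tab$class <- ifelse(comp_tab$n_edges >= 3, "complex", "simple")
    in_graph <- unique(c(edges$upper, edges$lower))
  } else {
    edges$comp <- integer(0)
    comp_tab <- data.frame(comp = integer(0), n_nodes = integer(0),
                           n_edges = integer(0), class = character(0))
    in_graph <- integer(0)
  }
  structure(list(edges = edges, components = comp_tab,
                 nodes = in_graph,
                 isolated = setdiff(all_nodes, in_graph)),
            class = "sym_graph")
}

#' @export
print.sym_graph <- function(x, ...) {
  cat(sprintf("<sym_graph> %d edges, %d components (%d complex), %d isolated peaks\n",
              nrow(x$edges), nrow(x$components),
              sum(x$components$class == "complex"), length(x$isolated)))
  invisible(x)
}

#' Export a symmetrization graph edge list and component summary
#'
#' @param sym a `sym_graph`.
#' @param path output path; the component summary is written to
#'   `<path>.components`.
#' @export
write_sym_graph <- function(sym, path) {
  write.table(sym$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sym$components, paste0(path, ".components"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# one maximum matching by augmenting paths (Kuhn's algorithm);
# edges: data.frame(upper, lower). Returns list(size, pairs).
max_bipartite_matching <- function(edges) {
  us <- unique(edges$upper)
  ls <- unique(edges$lower)
  adj <- split(match(edges$lower, ls), factor(match(edges$upper, us),
                                              levels = seq_along(us)))
  match_l <- rep(NA_integer_, length(ls))  # lower index -> upper index
  visited <- logical(length(ls))
  try_kuhn <- function(u) {
    for (l in adj[[u]]) {
      if (visited[l]) next
      visited[l] <<- TRUE
      if (is.na(match_l[l]) || try_kuhn(match_l[l])) {
        match_l[l] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0
  for (u in seq_along(us)) {
    visited <- logical(length(ls))
    if (try_kuhn(u)) size <- size + 1
  }
  list(size = size,
       pairs = data.frame(upper = us[match_l[!is.na(match_l)]],
                          lower = ls[!is.na(match_l)]))
}

#' Enumerate all maximum matchings of a bipartite component
#'
#' Exhaustively lists every matching of maximum cardinality of the
#' component, by branching on the possible partners of one node at a time
#' with a maximum-matching bound for pruning. The enumeration is capped;
#' components that exceed the cap stay unresolved and their NOE peaks are
#' not used as constraints.
#'
#' @param edges data.frame with columns `upper`, `lower` (one bipartite
#'   connected component).
#' @param cap maximum number of matchings to return.
#' @return list of matchings (each a data.frame upper/lower), with
#'   attribute `capped` = TRUE if the cap was hit (a warning is raised).
#' @export
enumerate_maximum_matchings <- function(edges, cap = 10000) {
  target <- max_bipartite_matching(edges)$size
  out <- vector("list", 64)
  n_out <- 0
  capped <- FALSE
  rec <- function(es, need, chosen) {
    if (capped) return()
    if (need == 0) {
      n_out <<- n_out + 1
      out[[n_out]] <<- chosen
      if (n_out >= cap) capped <<- TRUE
      return()
    }
    if (nrow(es) == 0) return()
    # branch on a node of minimum degree (small branching factor)
    du <- table(es$upper)
    dl <- table(es$lower)
    if (length(du) && (!length(dl) || min(du) <= min(dl))) {
      node <- as.integer(names(du)[which.min(du)])
      inc <- which(es$upper == node)
    } else {
      node <- as.integer(names(dl)[which.min(dl)])
      inc <- which(es$lower == node)
    }
    # case: node matched through each incident edge
    for (e in inc) {
      u <- es$upper[e]; l <- es$lower[e]
      rest <- es[es$upper != u & es$lower != l, , drop = FALSE]
      if (need - 1 == 0 ||
          (nrow(rest) > 0 && max_bipartite_matching(rest)$size >= need - 1))
        rec(rest, need - 1,
            rbind(chosen, data.frame(upper = u, lower = l)))
    }
    # case: node unmatched
    rest <- es[-inc, , drop = FALSE]
    if (nrow(rest) > 0 && max_bipartite_matching(rest)$size >= need)
      rec(rest, need, chosen)
  }
  rec(edges, target,
      data.frame(upper = integer(0), lower = integer(0)))
  if (capped)
    warning("maximum-matching enumeration cap (", cap,
            ") exceeded; component left unresolved")
  res <- out[seq_len(min(n_out, cap))]
  attr(res, "capped") <- capped
  attr(res, "size") <- target
  res
}
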