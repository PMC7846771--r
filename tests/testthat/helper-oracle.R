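# Independent brute-force oracle for the assignment semantics.
#
# Recomputes, with plain loops and exhaustive enumeration over injective
# peak-to-methyl maps (no CNF, no solver), the support set of every 2D
# peak under the full constraint semantics: annotation domains, geminal
# pairing, NOE clustering alternatives, symmetrization alternatives with
# the simple/complex component rules, and satisfiability-based reduction
# of complex components (satisfiability decided by map enumeration).
# Usable only at toy sizes.

oracle_domains <- function(peaks, mt) {
  lapply(seq_len(nrow(peaks)), function(i) {
    keep <- rep(TRUE, nrow(mt))
    tp <- peaks$allowed_types[i]
    if (tp != "any")
      keep <- keep & substr(mt$id, 1, 1) %in% strsplit(tp, "")[[1]]
    if (peaks$stereo[i] %in% c("proS", "proR"))
      keep <- keep & mt$stereo == peaks$stereo[i]
    if (!is.na(peaks$geminal_partner[i])) keep <- keep & !is.na(mt$geminal_id)
    if (!is.na(peaks$fixed_assignment[i]))
      keep <- keep & mt$id == peaks$fixed_assignment[i]
    which(keep)
  })
}

# all injective maps (lists of integer vectors peak_row -> methyl_row)
oracle_all_maps <- function(doms, n_methyls) {
  res <- list()
  rec <- function(i, cur, used) {
    if (i > length(doms)) {
      res[[length(res) + 1]] <<- cur
      return()
    }
    for (m in doms[[i]]) {
      if (used[m]) next
      used[m] <- TRUE
      rec(i + 1, c(cur, m), used)
      used[m] <- FALSE
    }
  }
  rec(1, integer(0), logical(n_methyls))
  res
}

oracle_pipeline <- function(graph, peaks, noesy_short, noesy_long, cfg) {
  mt <- graph$methyls
  nm <- nrow(mt)
  gem <- match(mt$geminal_id, mt$id)

  # edge compatibility lookup
  ia <- match(graph$edges$a, mt$id)
  ib <- match(graph$edges$b, mt$id)
  has_edge <- function(m1, m2, mixing) {
    sel <- (ia == m1 & ib == m2) | (ia == m2 & ib == m1)
    if (!any(sel)) return(FALSE)
    cls <- graph$edges$class[sel]
    if (mixing == "short") any(cls %in% c("geminal", "short")) else TRUE
  }

  # ---- network, re-derived with plain loops ----
  noes <- rbind(cbind(noesy_short, orig_id = noesy_short$noe_id),
                cbind(noesy_long, orig_id = noesy_long$noe_id))
  noes$noe_id <- seq_len(nrow(noes))
  keep <- abs(noes$c1 - noes$c2) >= cfg$diagonal_tol
  ret <- noes[keep, , drop = FALSE]
  ret$side <- ifelse(ret$c1 > ret$c2, "upper", "lower")
  cand <- lapply(seq_len(nrow(ret)), function(k) {
    hits <- integer(0)
    for (l in seq_len(nrow(peaks)))
      if (abs(ret$c2[k] - peaks$c_shift[l]) < cfg$c_tol &&
          abs(ret$h2[k] - peaks$h_shift[l]) < cfg$h_tol)
        hits <- c(hits, l)  # peak row index
    hits
  })
  names(cand) <- as.character(ret$noe_id)
  ret <- ret[lengths(cand) > 0, , drop = FALSE]
  cand <- cand[as.character(ret$noe_id)]

  edges <- data.frame(upper = integer(0), lower = integer(0))
  for (i in seq_len(nrow(ret))) for (j in seq_len(nrow(ret))) {
    if (ret$side[i] != "upper" || ret$side[j] != "lower") next
    if (ret$mixing_class[i] != ret$mixing_class[j]) next
    if (abs(ret$c2[i] - ret$c1[j]) < cfg$c_tol_sym &&
        abs(ret$c1[i] - ret$c2[j]) < cfg$c_tol_sym)
      edges <- rbind(edges, data.frame(upper = ret$noe_id[i],
                                       lower = ret$noe_id[j]))
  }

  mixing_of <- setNames(ret$mixing_class, as.character(ret$noe_id))

  # edge-level constraint: exists cluster choices making the mapped
  # methyls adjacent with the right class
  compat <- function(map, up, lo) {
    for (l in cand[[as.character(up)]]) for (lp in cand[[as.character(lo)]]) {
      if (map[l] != map[lp] &&
          has_edge(map[l], map[lp], mixing_of[[as.character(up)]]))
        return(TRUE)
    }
    FALSE
  }

  comp_split <- function(es) {
    # connected components by union-find over edge rows
    if (nrow(es) == 0) return(list())
    labs <- unique(c(paste0("u", es$upper), paste0("l", es$lower)))
    parent <- seq_along(labs)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(es))) {
      a <- find(match(paste0("u", es$upper[r]), labs))
      b <- find(match(paste0("l", es$lower[r]), labs))
      if (a != b) parent[a] <- b
    }
    roots <- vapply(seq_len(nrow(es)), function(r)
      find(match(paste0("u", es$upper[r]), labs)), integer(1))
    split(seq_len(nrow(es)), roots)
  }

  # all maximum matchings of a small edge set, by descending-size subset
  # enumeration
  all_mms <- function(es) {
    ne <- nrow(es)
    for (sz in ne:1) {
      found <- list()
      for (pick in utils::combn(ne, sz, simplify = FALSE)) {
        sub <- es[pick, , drop = FALSE]
        if (!anyDuplicated(sub$upper) && !anyDuplicated(sub$lower))
          found[[length(found) + 1]] <- sub
      }
      if (length(found)) return(found)
    }
    list()
  }

  doms <- oracle_domains(peaks, mt)
  valid_map <- function(map, simple_list, forced) {
    # annotation geminal pairing
    for (i in seq_len(nrow(peaks))) {
      gp <- peaks$geminal_partner[i]
      if (is.na(gp)) next
      pj <- match(gp, peaks$peak_id)
      if (is.na(gem[map[i]]) || gem[map[i]] != map[pj]) return(FALSE)
    }
    for (f in seq_len(nrow(forced)))
      if (!compat(map, forced$upper[f], forced$lower[f])) return(FALSE)
    for (sc in simple_list) {
      ok <- FALSE
      for (r in seq_len(nrow(sc)))
        if (compat(map, sc$upper[r], sc$lower[r])) { ok <- TRUE; break }
      if (!ok) return(FALSE)
    }
    TRUE
  }

  maps <- oracle_all_maps(doms, nm)
  no_force <- data.frame(upper = integer(0), lower = integer(0))
  sat_exists <- function(simple_list, forced) {
    for (map in maps) if (valid_map(map, simple_list, forced)) return(TRUE)
    FALSE
  }

  # ---- reduction fixpoint, mirroring the pass structure ----
  alive <- rep(TRUE, nrow(edges))
  simple_list <- list()
  simple_keys <- character(0)
  repeat {
    changed <- FALSE
    comps <- comp_split(edges[alive, , drop = FALSE])
    alive_idx <- which(alive)
    for (cp in comps) {
      rows <- alive_idx[cp]
      if (length(rows) < 3) next  # simple, handled below
      ce <- edges[rows, , drop = FALSE]
      surv <- rep(FALSE, nrow(ce))
      for (mm in all_mms(ce)) {
        hit <- paste(ce$upper, ce$lower) %in% paste(mm$upper, mm$lower)
        if (all(surv[hit])) next
        if (sat_exists(simple_list, mm)) surv <- surv | hit
      }
      if (!all(surv)) {
        alive[rows[!surv]] <- FALSE
        changed <- TRUE
      }
    }
    comps <- comp_split(edges[alive, , drop = FALSE])
    alive_idx <- which(alive)
    for (cp in comps) {
      rows <- alive_idx[cp]
      if (length(rows) > 2) next
      key <- paste(sort(rows), collapse = "+")
      if (key %in% simple_keys) next
      simple_list[[length(simple_list) + 1]] <- edges[rows, , drop = FALSE]
      simple_keys <- c(simple_keys, key)
      changed <- TRUE
    }
    if (!changed) break
  }
  # drop still-complex components from the constraint set (their peaks are
  # not used); simple_list already holds everything that constrains
  final_valid <- vapply(maps, valid_map, logical(1),
                        simple_list = simple_list, forced = no_force)
  vm <- maps[final_valid]
  if (length(vm) == 0) return(list(status = "unsat"))
  supports <- lapply(seq_len(nrow(peaks)), function(i)
    sort(unique(mt$id[vapply(vm, `[`, integer(1), i)])))
  names(supports) <- as.character(peaks$peak_id)
  list(status = "sat", supports = supports)
}

# TRUE when the instance is small enough for the subset-enumeration oracle
# (no symmetrization component with more than `max_edges` edges)
oracle_tractable <- function(peaks, noesy_short, noesy_long, cfg,
                             max_edges = 8) {
  net <- methylsat:::derive_network(cfg, peaks, noesy_short, noesy_long)
  nrow(net$sym$edges) == 0 || max(net$sym$components$n_edges) <= max_edges
}

# run the package pipeline on the same inputs and return comparable supports
package_supports <- function(graph, peaks, noesy_short, noesy_long, cfg) {
  res <- run_assignment(cfg, list(graph = graph, peaks2d = peaks,
                                  noesy_short = noesy_short,
                                  noesy_long = noesy_long))
  if (res$status != "assigned") return(list(status = "unsat"))
  list(status = "sat", supports = lapply(res$supports, sort))
}
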