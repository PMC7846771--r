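# Encoding the assignment problem in propositional logic and enumerating
# the complete per-peak support sets.
#
# Variables:
#   X(i, j)  2D reference peak i is assigned to methyl j
#   Y(k, l)  NOE cross-peak k is clustered to 2D peak l
#   Z(k, k') NOE peaks k (upper-diagonal) and k' (lower-diagonal) are truly
#            symmetric, i.e. report the same connectivity
#
# Hard constraints:
#   (1) exactly one X(i, .) per peak          (every peak has one methyl)
#   (2) at most one X(., j) per methyl        (no methyl used twice)
#   (3) exactly one Y(k, .) per NOE in the symmetrization graph
#   (4) Z respects the symmetrization graph: forced for size-2 simple
#       components, exactly-one over the two alternatives for size-3;
#       complex components only contribute after satisfiability reduction
#   (5) Z(k,k') & Y(k,l) & Y(k',l') & X(l,m) -> some X(l',m') with (m,m')
#       an edge of the structure graph of a class compatible with the
#       mixing time (short-mixing NOEs need a geminal or short-range edge,
#       long-mixing NOEs any edge)
# plus geminal-pair annotations (partner peaks map to the two methyls of
# one Leu/Val residue) and fixed assignments as unit clauses.
#
# Constraint (5) is emitted in the standard subgraph-isomorphism support
# form: conditioned on X(l,m), a clause requires a compatible neighbour
# assignment on l'. Given the exactly-one constraint on l', this is
# equivalent to blocking each incompatible methyl pair, at a fraction of
# the clause count.
#
# Simple-component symmetry constraints are guarded by selector variables
# (one per component) that are passed as assumptions to every solver call;
# this is what allows UNSAT diagnostics to identify conflicting NOE groups
# without rebuilding the formula.

# ---- clause accumulation -------------------------------------------------

new_cnf <- function() {
  b <- new.env(parent = emptyenv())
  b$nv <- 0L
  b$buf <- .cbuf_new()  # clause storage lives on the C++ side (O(1) append)
  b
}

cnf_var <- function(b, n = 1L) {
  v <- b$nv + seq_len(n)
  b$nv <- b$nv + as.integer(n)
  v
}

cnf_clause <- function(b, lits) {
  .cbuf_push(b$buf, as.integer(lits))
  invisible(NULL)
}

# materialize the clause list of an encoded instance (tests, DIMACS dump)
cnf_clause_list <- function(instance) .cbuf_as_list(instance$buf)

cnf_at_most_one <- function(b, vars) {
  n <- length(vars)
  if (n <= 1) return(invisible(NULL))
  if (n <= 30) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
      cnf_clause(b, c(-vars[i], -vars[j]))
  } else {
    # sequential (ladder) encoding: s_i = "one of vars[1..i] is true"
    s <- cnf_var(b, n - 1L)
    cnf_clause(b, c(-vars[1], s[1]))
    for (i in 2:(n - 1)) {
      cnf_clause(b, c(-vars[i], s[i]))
      cnf_clause(b, c(-s[i - 1], s[i]))
      cnf_clause(b, c(-vars[i], -s[i - 1]))
    }
    cnf_clause(b, c(-vars[n], -s[n - 1]))
  }
  invisible(NULL)
}

cnf_exactly_one <- function(b, vars) {
  stopifnot(length(vars) >= 1)
  cnf_clause(b, vars)
  cnf_at_most_one(b, vars)
}

#' Write a CNF formula in DIMACS format
#'
#' For external verification of the encoded instance with any standard
#' satisfiability solver.
#'
#' @param instance a `cnf_instance` (from [encode_assignment()]) or an
#'   engine environment.
#' @param path output path.
#' @export
write_dimacs <- function(instance, path) {
  if (is.environment(instance)) instance <- instance$instance
  cl <- cnf_clause_list(instance)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("p cnf %d %d", instance$nvars, length(cl)), con)
  writeLines(vapply(cl, function(x) paste(c(x, 0L), collapse = " "),
                    character(1)), con)
  invisible(path)
}

# ---- domains -------------------------------------------------------------

# Allowed methyls per 2D peak from its annotations, as indices into the
# methyl table. Geminal-pair annotations are propagated to a fixpoint:
# a methyl stays in a peak's domain only if its geminal sibling is in the
# partner peak's domain.
peak_domains <- function(peaks2d, methyl_tab) {
  n <- nrow(peaks2d)
  res_letter <- RES1[methyl_tab$res_type]
  doms <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- rep(TRUE, nrow(methyl_tab))
    tp <- peaks2d$allowed_types[i]
    if (tp != "any")
      keep <- keep & res_letter %in% strsplit(tp, "")[[1]]
    st <- peaks2d$stereo[i]
    if (st %in% c("proS", "proR"))
      keep <- keep & methyl_tab$stereo == st
    if (!is.na(peaks2d$geminal_partner[i]))
      keep <- keep & !is.na(methyl_tab$geminal_id)
    fx <- peaks2d$fixed_assignment[i]
    if (!is.na(fx)) {
      j <- match(fx, methyl_tab$id)
      if (is.na(j))
        stop("peak ", peaks2d$peak_id[i], ": fixed assignment ", fx,
             " is not a methyl of the structure")
      keep <- keep & seq_len(nrow(methyl_tab)) == j
    }
    doms[[i]] <- which(keep)
  }
  # geminal fixpoint
  gem_idx <- match(methyl_tab$geminal_id, methyl_tab$id)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      gp <- peaks2d$geminal_partner[i]
      if (is.na(gp)) next
      pj <- match(gp, peaks2d$peak_id)
      ok <- !is.na(gem_idx[doms[[i]]]) & gem_idx[doms[[i]]] %in% doms[[pj]]
      if (!all(ok)) {
        doms[[i]] <- doms[[i]][ok]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (i in seq_len(n))
    if (length(doms[[i]]) == 0)
      stop("peak ", peaks2d$peak_id[i],
           ": annotations exclude every methyl of the structure")
  doms
}

# ---- encoding ------------------------------------------------------------

#' Encode an assignment problem as a CNF instance
#'
#' Builds the full Boolean formula over X/Y/Z variables for a structure
#' graph, an annotated 2D reference peak list, the NOE cluster map and the
#' symmetrization graph. Simple-component symmetry constraints are guarded
#' by selector variables (returned in `guards`) which must be assumed true
#' in every solver call; complex components receive free Z variables that
#' only constrain the formula when assumed (see
#' [reduce_complex_components()]).
#'
#' @param graph a `structure_graph`.
#' @param peaks2d a `peak2d_list`.
#' @param noes combined retained NOE table (with `diagonal_side`,
#'   `mixing_class`).
#' @param cluster result of [cluster_noes()].
#' @param sym a `sym_graph` over `noes`.
#' @return a `cnf_instance` list: `nvars`, `clauses`, variable indices
#'   (`x`, `y`, `z`), `guards`, `domains`, and the input objects.
#' @export
encode_assignment <- function(graph, peaks2d, noes, cluster, sym) {
  methyl_tab <- graph$methyls
  n_peaks <- nrow(peaks2d)
  n_methyls <- nrow(methyl_tab)
  if (n_peaks > n_methyls)
    stop("more 2D reference peaks (", n_peaks, ") than labeled methyls (",
         n_methyls, ")")
  doms <- peak_domains(peaks2d, methyl_tab)

  b <- new_cnf()

  # X variables and families (1), (2)
  x <- vector("list", n_peaks)
  for (i in seq_len(n_peaks)) {
    v <- cnf_var(b, length(doms[[i]]))
    names(v) <- methyl_tab$id[doms[[i]]]
    x[[i]] <- v
  }
  for (i in seq_len(n_peaks)) cnf_exactly_one(b, x[[i]])
  for (j in seq_len(n_methyls)) {
    vs <- integer(0)
    for (i in seq_len(n_peaks)) {
      p <- match(j, doms[[i]])
      if (!is.na(p)) vs <- c(vs, x[[i]][p])
    }
    cnf_at_most_one(b, vs)
  }

  # fixed assignments as unit clauses
  for (i in seq_len(n_peaks)) {
    fx <- peaks2d$fixed_assignment[i]
    if (!is.na(fx)) cnf_clause(b, x[[i]][[fx]])
  }

  # geminal 2D annotations: X(i,m) -> X(partner, geminal sibling of m)
  gem_idx <- match(methyl_tab$geminal_id, methyl_tab$id)
  for (i in seq_len(n_peaks)) {
    gp <- peaks2d$geminal_partner[i]
    if (is.na(gp)) next
    pj <- match(gp, peaks2d$peak_id)
    for (p in seq_along(doms[[i]])) {
      m <- doms[[i]][p]
      sib <- gem_idx[m]
      q <- match(sib, doms[[pj]])
      cnf_clause(b, c(-x[[i]][p], x[[pj]][q]))
    }
  }

  # Y variables and family (3), for NOEs that appear in the symmetrization
  # graph (others impose no constraint)
  y <- list()
  for (k in sym$nodes) {
    cand <- cluster$candidates[[as.character(k)]]
    v <- cnf_var(b, length(cand))
    names(v) <- as.character(cand)
    y[[as.character(k)]] <- v
    cnf_exactly_one(b, v)
  }

  # Z variables, one per symmetrization edge
  ztab <- sym$edges
  if (nrow(ztab)) ztab$var <- cnf_var(b, nrow(ztab)) else ztab$var <- integer(0)

  # family (4): guarded constraints for simple components
  guards <- integer(0)
  guard_comp <- integer(0)
  for (ci in seq_len(nrow(sym$components))) {
    if (sym$components$class[ci] != "simple") next
    zc <- ztab$var[ztab$comp == sym$components$comp[ci]]
    g <- cnf_var(b)
    cnf_clause(b, c(-g, zc))
    if (length(zc) == 2) cnf_clause(b, c(-zc[1], -zc[2]))
    guards <- c(guards, g)
    guard_comp <- c(guard_comp, sym$components$comp[ci])
  }

  # family (5): structural compatibility of symmetric NOE pairs
  peak_pos <- function(pid) match(pid, peaks2d$peak_id)
  adj <- structure_adjacency(graph)
  for (e in seq_len(nrow(ztab))) {
    k <- ztab$upper[e]; kp <- ztab$lower[e]
    zl <- ztab$var[e]
    neigh <- if (noes$mixing_class[match(k, noes$noe_id)] == "short")
      adj$short else adj$all
    yk <- y[[as.character(k)]]
    ykp <- y[[as.character(kp)]]
    for (a in seq_along(yk)) {
      l <- peak_pos(as.integer(names(yk)[a]))
      for (bb in seq_along(ykp)) {
        lp <- peak_pos(as.integer(names(ykp)[bb]))
        for (p in seq_along(doms[[l]])) {
          m <- doms[[l]][p]
          ok <- intersect(neigh[[m]], doms[[lp]])
          cnf_clause(b, c(-zl, -yk[a], -ykp[bb], -x[[l]][p],
                          x[[lp]][match(ok, doms[[lp]])]))
        }
      }
    }
  }

  list(nvars = b$nv, buf = b$buf, n_clauses = .cbuf_size(b$buf),
       x = x, y = y, z = ztab, guards = guards, guard_comp = guard_comp,
       domains = doms, graph = graph, peaks2d = peaks2d, noes = noes,
       cluster = cluster, sym = sym)
}

# adjacency lists by compatibility class: indices into the methyl table
structure_adjacency <- function(graph) {
  tab <- graph$methyls
  n <- nrow(tab)
  ia <- match(graph$edges$a, tab$id)
  ib <- match(graph$edges$b, tab$id)
  short_ok <- graph$edges$class %in% c("geminal", "short")
  adj_all <- vector("list", n)
  adj_short <- vector("list", n)
  for (e in seq_along(ia)) {
    adj_all[[ia[e]]] <- c(adj_all[[ia[e]]], ib[e])
    adj_all[[ib[e]]] <- c(adj_all[[ib[e]]], ia[e])
    if (short_ok[e]) {
      adj_short[[ia[e]]] <- c(adj_short[[ia[e]]], ib[e])
      adj_short[[ib[e]]] <- c(adj_short[[ib[e]]], ia[e])
    }
  }
  list(all = lapply(adj_all, function(v) if (is.null(v)) integer(0) else v),
       short = lapply(adj_short, function(v) if (is.null(v)) integer(0) else v))
}

# ---- solver engine -------------------------------------------------------

#' Create a solver engine for an encoded instance
#'
#' Loads the CNF into the package's CDCL solver. The engine is an
#' environment so that reduction and enumeration can add clauses
#' incrementally.
#'
#' @param instance a `cnf_instance` from [encode_assignment()].
#' @param max_conflicts per-call conflict budget (-1 = unlimited); if the
#'   budget is hit the call reports status `"undetermined"`, never UNSAT.
#' @return an engine environment.
#' @export
sat_engine <- function(instance, max_conflicts = -1) {
  e <- new.env(parent = emptyenv())
  e$ptr <- .sat_new(as.integer(instance$nvars))
  .sat_add_buffer(e$ptr, instance$buf)
  e$instance <- instance
  e$assumptions <- instance$guards
  e$max_conflicts <- max_conflicts
  e$n_calls <- 0L
  e
}

engine_solve <- function(engine, extra_assumptions = integer(0)) {
  engine$n_calls <- engine$n_calls + 1L
  .sat_solve(engine$ptr,
             as.integer(c(engine$assumptions, extra_assumptions)),
             engine$max_conflicts)
}

engine_add_clause <- function(engine, lits) {
  .sat_add_clause(engine$ptr, as.integer(lits))
}

engine_new_var <- function(engine) .sat_new_var(engine$ptr)

# model (0/1 vector) -> named character vector peak_id -> methyl id
model_mapping <- function(instance, model) {
  vapply(seq_along(instance$x), function(i) {
    v <- instance$x[[i]]
    names(v)[model[v] == 1][1]
  }, character(1))
}

#' Solve an encoded instance once
#'
#' Returns one satisfying assignment (as a peak-to-methyl mapping) or an
#' UNSAT / undetermined verdict.
#'
#' @param engine engine from [sat_engine()].
#' @return list with `status` ("sat", "unsat", "undetermined"), and for
#'   "sat" a `mapping` (named character vector peak_id -> methyl id) and the
#'   raw `model`.
#' @export
solve_once <- function(engine) {
  r <- engine_solve(engine)
  if (r$status != "sat") return(list(status = r$status))
  mapping <- model_mapping(engine$instance, r$model)
  names(mapping) <- as.character(engine$instance$peaks2d$peak_id)
  list(status = "sat", mapping = mapping, model = r$model)
}

# ---- complex-component reduction ----------------------------------------

#' Reduce complex symmetrization components by explicit satisfiability
#'
#' For every complex component, all maximum matchings (MMs) are enumerated
#' and each MM is adopted as a set of assumed-true Z variables on top of
#' the current formula. An edge survives iff it belongs to at least one MM
#' whose adoption is satisfiable; eliminated edges are fixed false and the
#' component structure is recomputed, iterating to a fixpoint. Components
#' that decompose into simple ones contribute their NOEs as constraints;
#' components that remain complex (or exceed the enumeration cap) are left
#' unresolved and their peaks are not used.
#'
#' @param engine engine from [sat_engine()].
#' @param mm_cap maximum matchings enumerated per component.
#' @return (invisibly) the engine, with fields `final_sym` (reduced
#'   symmetrization graph), `unresolved_comp_noes` and updated assumptions.
#' @export
reduce_complex_components <- function(engine, mm_cap = 10000) {
  inst <- engine$instance
  zt <- inst$z
  all_nodes <- inst$sym$nodes  # only nodes that had at least one edge
  alive <- rep(TRUE, nrow(zt))
  constrained <- rep(FALSE, nrow(zt))  # edge already under a simple-comp guard
  unresolved_edges <- rep(FALSE, nrow(zt))

  # edges of originally simple components are constrained from the start
  simple0 <- inst$sym$components$comp[inst$sym$components$class == "simple"]
  constrained[zt$comp %in% simple0] <- TRUE

  zkey <- paste(zt$upper, zt$lower)
  repeat {
    changed <- FALSE
    cur <- classify_sym_graph(zt[alive & !unresolved_edges,
                                 c("upper", "lower", "mixing_class"),
                                 drop = FALSE], all_nodes)
    if (nrow(cur$edges) == 0) break
    ckey <- paste(cur$edges$upper, cur$edges$lower)
    for (ci in seq_len(nrow(cur$components))) {
      if (cur$components$class[ci] != "complex") next
      ce <- cur$edges[cur$edges$comp == cur$components$comp[ci], , drop = FALSE]
      mms <- enumerate_maximum_matchings(ce[, c("upper", "lower")], cap = mm_cap)
      if (isTRUE(attr(mms, "capped"))) {
        unresolved_edges[match(paste(ce$upper, ce$lower), zkey)] <- TRUE
        changed <- TRUE
        next
      }
      surv <- character(0)
      for (mm in mms) {
        mk <- paste(mm$upper, mm$lower)
        if (all(mk %in% surv)) next  # already known satisfiable
        zv <- zt$var[match(mk, zkey)]
        r <- engine_solve(engine, zv)
        if (r$status == "undetermined") {
          unresolved_edges[match(paste(ce$upper, ce$lower), zkey)] <- TRUE
          surv <- character(0)
          break
        }
        if (r$status == "sat") surv <- union(surv, mk)
      }
      dead <- setdiff(paste(ce$upper, ce$lower), surv)
      if (length(dead) && !all(unresolved_edges[match(paste(ce$upper, ce$lower),
                                                      zkey)])) {
        idx <- match(dead, zkey)
        alive[idx] <- FALSE
        for (ii in idx) engine_add_clause(engine, -zt$var[ii])
        changed <- TRUE
      }
    }
    # components that are now simple but not yet constrained get a guard
    cur <- classify_sym_graph(zt[alive & !unresolved_edges,
                                 c("upper", "lower", "mixing_class"),
                                 drop = FALSE], all_nodes)
    ckey <- paste(cur$edges$upper, cur$edges$lower)
    for (ci in seq_len(nrow(cur$components))) {
      if (cur$components$class[ci] != "simple") next
      sel <- cur$edges$comp == cur$components$comp[ci]
      idx <- match(ckey[sel], zkey)
      if (all(constrained[idx])) next
      zv <- zt$var[idx]
      g <- engine_new_var(engine)
      engine_add_clause(engine, c(-g, zv))
      if (length(zv) == 2) engine_add_clause(engine, c(-zv[1], -zv[2]))
      engine$assumptions <- c(engine$assumptions, g)
      engine$instance$guards <- c(engine$instance$guards, g)
      engine$instance$guard_comp <- c(engine$instance$guard_comp, NA_integer_)
      constrained[idx] <- TRUE
      changed <- TRUE
    }
    if (!changed) break
  }

  # finalize: still-complex or unresolved edges are not used
  final <- classify_sym_graph(zt[alive & !unresolved_edges,
                                 c("upper", "lower", "mixing_class"),
                                 drop = FALSE], all_nodes)
  fkey <- paste(final$edges$upper, final$edges$lower)
  still_complex <- final$components$comp[final$components$class == "complex"]
  drop_keys <- fkey[final$edges$comp %in% still_complex]
  for (k in match(drop_keys, zkey)) {
    alive[k] <- FALSE
    engine_add_clause(engine, -zt$var[k])
  }
  for (k in which(unresolved_edges & alive)) {
    alive[k] <- FALSE
    engine_add_clause(engine, -zt$var[k])
  }
  used_final <- classify_sym_graph(zt[alive, c("upper", "lower",
                                               "mixing_class"), drop = FALSE],
                                   all_nodes)
  engine$final_sym <- used_final
  engine$unresolved_comp_noes <-
    setdiff(all_nodes, used_final$nodes)
  invisible(engine)
}

# ---- support-set enumeration --------------------------------------------

#' Enumerate the exhaustive per-peak support sets
#'
#' Implements the iterative enumeration ansatz: obtain one valid global
#' mapping, then for one peak at a time repeatedly forbid its already-found
#' options (as assumptions) and re-solve until unsatisfiable; the options
#' collected are exactly the methyls this peak takes in some global
#' solution. The peak's domain is then frozen to its support before moving
#' to the next peak (which does not change the global solution set, since
#' the support already contains every value the peak takes in any model).
#' Peaks are processed in ascending domain-size order. Every model found
#' along the way also seeds the supports of all other peaks, so the number
#' of solver calls stays close to the sum of the support sizes.
#'
#' @param engine engine from [sat_engine()] (after
#'   [reduce_complex_components()] in the full pipeline).
#' @return list with `status` and, when satisfiable, `supports`: a named
#'   list (by peak id) of character vectors of methyl ids, plus
#'   `ambiguity`: factor with levels unique / 2-3 / >3.
#' @export
enumerate_support_sets <- function(engine) {
  inst <- engine$instance
  n <- length(inst$x)
  r <- engine_solve(engine)
  if (r$status != "sat") return(list(status = r$status))
  supports <- vector("list", n)
  seed <- function(model) {
    for (i in seq_len(n)) {
      v <- inst$x[[i]]
      supports[[i]] <<- union(supports[[i]], names(v)[model[v] == 1])
    }
  }
  seed(r$model)
  ord <- order(lengths(inst$domains))
  for (i in ord) {
    v <- inst$x[[i]]
    repeat {
      if (length(supports[[i]]) == length(v)) break  # full domain reached
      excl <- -v[supports[[i]]]
      r <- engine_solve(engine, excl)
      if (r$status == "undetermined") return(list(status = "undetermined"))
      if (r$status == "unsat") break
      seed(r$model)
    }
    engine_add_clause(engine, v[supports[[i]]])
  }
  names(supports) <- as.character(inst$peaks2d$peak_id)
  amb <- vapply(supports, function(s) {
    if (length(s) == 1) "unique" else if (length(s) <= 3) "2-3" else ">3"
  }, character(1))
  list(status = "sat", supports = supports,
       ambiguity = amb, n_solver_calls = engine$n_calls)
}

# ---- UNSAT diagnostics ---------------------------------------------------

# Best-effort identification of conflicting symmetry-constraint groups:
# components whose single removal restores satisfiability, or a greedily
# grown conflict set. Returns a character description vector.
diagnose_unsat <- function(engine) {
  inst <- engine$instance
  guards <- engine$assumptions
  if (length(guards) == 0)
    return(paste("the reference-peak annotations alone are unsatisfiable",
                 "(residue types, geminal pairs or fixed assignments",
                 "conflict with the structure)"))
  r0 <- engine_solve_with(engine, integer(0))
  if (r0$status == "unsat")
    return(paste("unsatisfiable even without any NOE symmetry constraints:",
                 "check residue types, geminal pairs and fixed assignments"))
  msgs <- character(0)
  for (g in seq_along(guards)) {
    r <- engine_solve_with(engine, guards[-g])
    if (r$status == "sat")
      msgs <- c(msgs, sprintf(
        "removing NOE symmetry-component constraint %d restores satisfiability (NOEs: %s)",
        g, guard_noes(engine, g)))
  }
  if (length(msgs) == 0) {
    keep <- integer(0)
    for (g in seq_along(guards)) {
      r <- engine_solve_with(engine, c(keep, guards[g]))
      if (r$status != "sat")
        msgs <- c(msgs, sprintf(
          "NOE symmetry-component constraint %d (NOEs: %s) joins a conflicting set",
          g, guard_noes(engine, g)))
      else keep <- c(keep, guards[g])
    }
  }
  msgs
}

engine_solve_with <- function(engine, assumptions) {
  engine$n_calls <- engine$n_calls + 1L
  .sat_solve(engine$ptr, as.integer(assumptions), engine$max_conflicts)
}

guard_noes <- function(engine, g) {
  comp <- engine$instance$guard_comp[g]
  if (is.na(comp)) return("recovered from a complex component")
  ed <- engine$instance$z[engine$instance$z$comp == comp, , drop = FALSE]
  paste(unique(c(ed$upper, ed$lower)), collapse = ",")
}
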