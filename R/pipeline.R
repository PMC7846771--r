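# Full-run orchestration: structure graph -> peak lists -> NOE network ->
# complex-component reduction -> support-set enumeration -> report, plus
# the short-radius optimization protocol and iterative re-runs with
# user-fixed assignments.

#' Assemble a run configuration
#'
#' @param short_radius,long_radius structure-graph radii in Angstrom
#'   (recommended 6-8 and 10-12).
#' @param c_tol,h_tol clustering tolerances in ppm.
#' @param c_tol_sym symmetrization 13C tolerance in ppm.
#' @param diagonal_tol diagonal-elimination 13C tolerance in ppm.
#' @param scheme labeling scheme code.
#' @param oligomer_chains chains to collapse as identical subunits, or
#'   NULL.
#' @param classify engage the chemical-shift residue-type classifier for
#'   peaks with no residue-type annotation.
#' @param mm_cap maximum-matching enumeration cap per component.
#' @param max_conflicts solver conflict budget per call (-1 unlimited).
#' @param force bypass the recommended-range check on radii.
#' @param seed seed recorded in outputs (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(short_radius = 8, long_radius = 10,
                       c_tol = 0.15, h_tol = 0.02, c_tol_sym = 0.15,
                       diagonal_tol = 0.15, scheme = "ILV",
                       oligomer_chains = NULL, classify = FALSE,
                       mm_cap = 10000, max_conflicts = -1,
                       force = FALSE, seed = NULL) {
  stopifnot(c_tol > 0, h_tol > 0, c_tol_sym > 0, diagonal_tol >= 0)
  cfg <- list(short_radius = short_radius, long_radius = long_radius,
              c_tol = c_tol, h_tol = h_tol, c_tol_sym = c_tol_sym,
              diagonal_tol = diagonal_tol, scheme = scheme,
              oligomer_chains = oligomer_chains, classify = classify,
              mm_cap = mm_cap, max_conflicts = max_conflicts,
              force = force, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

# normalize the various accepted input forms into a structure graph +
# peak tables
resolve_inputs <- function(config, inputs) {
  graph <- inputs$graph
  if (is.null(graph)) {
    structure_models <- inputs$structure
    if (is.character(structure_models))
      structure_models <- read_structure(structure_models)
    methyls <- inputs$methyls
    if (is.null(methyls))
      methyls <- extract_methyls(structure_models, config$scheme,
                                 inputs$sequence)
    graph <- build_structure_graph(methyls,
                                   short_radius = config$short_radius,
                                   long_radius = config$long_radius,
                                   oligomer_chains = config$oligomer_chains,
                                   force = config$force)
  }
  peaks2d <- inputs$peaks2d
  if (is.character(peaks2d))
    peaks2d <- read_hmqc(peaks2d, dialect = inputs$dialect %||% "native")
  noes_s <- inputs$noesy_short
  if (is.character(noes_s)) noes_s <- read_noesy(noes_s, "short")
  noes_l <- inputs$noesy_long
  if (is.character(noes_l)) noes_l <- read_noesy(noes_l, "long")
  if (isTRUE(config$classify)) {
    unann <- peaks2d$allowed_types == "any"
    if (any(unann))
      peaks2d$allowed_types[unann] <-
        classify_residue_type(peaks2d$c_shift[unann], peaks2d$h_shift[unann])
  }
  list(graph = graph, peaks2d = peaks2d,
       noesy_short = noes_s, noesy_long = noes_l)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive the NOE network (combined short+long with global noe keys),
# cluster map and symmetrization graph; shared by assignment and radius
# probing
derive_network <- function(config, peaks2d, noesy_short, noesy_long) {
  noes <- rbind(
    if (!is.null(noesy_short) && nrow(noesy_short))
      cbind(noesy_short, orig_id = noesy_short$noe_id) else NULL,
    if (!is.null(noesy_long) && nrow(noesy_long))
      cbind(noesy_long, orig_id = noesy_long$noe_id) else NULL)
  if (is.null(noes) || nrow(noes) == 0)
    stop("no NOE peaks supplied")
  noes$noe_id <- seq_len(nrow(noes))
  de <- eliminate_diagonal(noes, config$diagonal_tol)
  cl <- cluster_noes(de$retained, peaks2d, config$c_tol, config$h_tol)
  clustered <- de$retained[!(de$retained$noe_id %in% cl$unclustered), ,
                           drop = FALSE]
  sym <- build_symmetrization_graph(clustered, config$c_tol_sym,
                                    h_tol_sym = config$h_tol)
  list(noes = noes, retained = de$retained, diagonal = de$eliminated,
       cluster = cl, clustered = clustered, sym = sym)
}

#' Run the full assignment pipeline
#'
#' Builds the structure graph, derives the NOE network, reduces complex
#' symmetrization components by explicit satisfiability and enumerates the
#' complete per-peak support sets. An unsatisfiable input is a reported
#' outcome (with diagnostics), not an error.
#'
#' @param config a [run_config()].
#' @param inputs list with either `graph` (a `structure_graph`) or
#'   `structure` (path or `structure_models`) plus `sequence`; and
#'   `peaks2d`, `noesy_short`, `noesy_long` (paths or parsed tables).
#' @return object of class `assignment_result`: `status`, `supports`,
#'   `ambiguity`, `noe_annotations`, `stats`, `diagnostics`, `config`.
#' @export
run_assignment <- function(config, inputs) {
  ri <- resolve_inputs(config, inputs)
  net <- derive_network(config, ri$peaks2d, ri$noesy_short, ri$noesy_long)
  inst <- encode_assignment(ri$graph, ri$peaks2d, net$clustered,
                            net$cluster, net$sym)
  engine <- sat_engine(inst, max_conflicts = config$max_conflicts)
  reduce_complex_components(engine, mm_cap = config$mm_cap)
  enum <- enumerate_support_sets(engine)

  ann <- annotate_noes(net, engine, ri$peaks2d, ri$graph)
  if (enum$status != "sat") {
    diags <- if (enum$status == "unsat") diagnose_unsat(engine) else
      "solver conflict budget exhausted; result undetermined, not unsatisfiable"
    res <- list(status = enum$status, supports = NULL, ambiguity = NULL,
                noe_annotations = ann, stats = NULL, diagnostics = diags,
                config = config, graph = ri$graph, peaks2d = ri$peaks2d,
                n_solver_calls = engine$n_calls)
    class(res) <- "assignment_result"
    return(res)
  }
  stats <- support_stats(enum$supports)
  res <- list(status = "assigned", supports = enum$supports,
              ambiguity = enum$ambiguity, noe_annotations = ann,
              stats = stats, diagnostics = character(0), config = config,
              graph = ri$graph, peaks2d = ri$peaks2d,
              n_solver_calls = engine$n_calls)
  class(res) <- "assignment_result"
  res
}

# per-NOE bookkeeping: how each cross-peak was used
annotate_noes <- function(net, engine, peaks2d, graph) {
  noes <- net$noes
  status <- rep(NA_character_, nrow(noes))
  status[noes$noe_id %in% net$diagonal] <- "diagonal"
  status[noes$noe_id %in% net$cluster$unclustered] <- "unclustered"
  in_sym <- net$sym$nodes
  status[is.na(status) & !(noes$noe_id %in% in_sym)] <- "no_symmetric_partner"
  used_nodes <- engine$final_sym$nodes
  status[is.na(status) & noes$noe_id %in% engine$unresolved_comp_noes] <-
    "unresolved_complex_component"
  status[is.na(status) & noes$noe_id %in% used_nodes] <- "used"
  # used NOEs between annotated geminal 2D partners
  gem_pairs <- peaks2d$peak_id[!is.na(peaks2d$geminal_partner)]
  for (k in which(status == "used")) {
    id <- noes$noe_id[k]
    cand <- net$cluster$candidates[[as.character(id)]]
    partners <- engine$final_sym$edges
    mir <- c(partners$lower[partners$upper == id],
             partners$upper[partners$lower == id])
    mir_cand <- unique(unlist(net$cluster$candidates[as.character(mir)]))
    if (length(cand) && length(mir_cand) &&
        all(cand %in% gem_pairs) &&
        all(peaks2d$geminal_partner[match(cand, peaks2d$peak_id)] %in%
              mir_cand))
      status[k] <- "geminal"
  }
  partners_of <- function(id) {
    e <- engine$final_sym$edges
    paste(unique(c(e$lower[e$upper == id], e$upper[e$lower == id])),
          collapse = ",")
  }
  data.frame(
    mixing_class = noes$mixing_class,
    noe_id = noes$orig_id,
    c1 = noes$c1, c2 = noes$c2, h2 = noes$h2,
    clustered_to = vapply(noes$noe_id, function(id) {
      cand <- net$cluster$candidates[[as.character(id)]]
      if (is.null(cand)) "" else paste(cand, collapse = ",")
    }, character(1)),
    symmetric_partner = vapply(noes$noe_id, partners_of, character(1)),
    status = status,
    stringsAsFactors = FALSE)
}

support_stats <- function(supports) {
  n <- length(supports)
  sizes <- lengths(supports)
  data.frame(
    category = c("unique", "2-3 options", ">3 options", "unassigned"),
    n = c(sum(sizes == 1), sum(sizes %in% 2:3), sum(sizes > 3),
          sum(sizes == 0)),
    percent = round(100 * c(sum(sizes == 1), sum(sizes %in% 2:3),
                            sum(sizes > 3), sum(sizes == 0)) / n, 1))
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> status: %s\n", x$status))
  if (x$status == "assigned") {
    print(x$stats, row.names = FALSE)
    cat(sprintf("(%d solver calls)\n", x$n_solver_calls))
  } else if (length(x$diagnostics)) {
    cat("diagnostics:\n")
    cat(paste0("  - ", x$diagnostics, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write the assignment report files
#'
#' Emits `support_options.tsv` (per-peak assignment option lists),
#' `noe_annotations.tsv` (how every NOE cross-peak was used),
#' `summary.tsv` (assignment statistics), `support_sets.json`
#' (machine-readable) and `config.txt` (the full configuration echo).
#'
#' @param result an `assignment_result`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$supports)) {
    opt <- data.frame(
      peak_id = names(result$supports),
      n_options = lengths(result$supports),
      ambiguity = result$ambiguity,
      options = vapply(result$supports, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    write.table(opt, file.path(dir, "support_options.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(result$stats, file.path(dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(result$supports,
                         file.path(dir, "support_sets.json"))
  }
  write.table(result$noe_annotations, file.path(dir, "noe_annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- result$config
  cfg$oligomer_chains <- paste(cfg$oligomer_chains, collapse = ",")
  writeLines(c(sprintf("status\t%s", result$status),
               vapply(names(cfg), function(k)
                 sprintf("%s\t%s", k, paste(format(cfg[[k]]), collapse = ",")),
                 character(1)),
               if (length(result$diagnostics))
                 paste0("diagnostic\t", result$diagnostics)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Optimize the short-mixing distance threshold
#'
#' Starts from the standard 8 Angstrom threshold for the short-mixing NOE
#' data (assumed to be the maximum observable 50 ms NOE distance), lowers
#' it in 0.1 Angstrom steps until the NOE network no longer fits the
#' structure graph, and returns the smaller of (minimum satisfiable
#' threshold + 0.5) and 8.0. Each probe is a single satisfiability check,
#' not an enumeration.
#'
#' @param config a [run_config()] (its `short_radius` is ignored; probing
#'   starts at `start` regardless).
#' @param inputs as for [run_assignment()].
#' @param start starting threshold in Angstrom.
#' @param step probe step in Angstrom.
#' @param floor_radius smallest threshold probed.
#' @return list with `radius` (the chosen threshold), `d_min` (smallest
#'   satisfiable threshold found) and `probes` (data.frame radius/status).
#' @export
optimize_short_radius <- function(config, inputs, start = 8.0, step = 0.1,
                                  floor_radius = 2.0) {
  ri <- resolve_inputs(config, inputs)
  net <- derive_network(config, ri$peaks2d, ri$noesy_short, ri$noesy_long)
  probe <- function(r) {
    g <- reclassify_structure_graph(ri$graph, short_radius = r,
                                    long_radius = config$long_radius)
    inst <- encode_assignment(g, ri$peaks2d, net$clustered, net$cluster,
                              net$sym)
    engine <- sat_engine(inst, max_conflicts = config$max_conflicts)
    reduce_complex_components(engine, mm_cap = config$mm_cap)
    engine_solve(engine)$status
  }
  st <- probe(start)
  if (st == "unsat")
    stop("unsatisfiable at the standard ", start, " Angstrom threshold; ",
         "check the input peak lists and annotations before optimizing")
  if (st == "undetermined")
    stop("solver budget exhausted at the starting threshold")
  probes <- data.frame(radius = start, status = st)
  d_min <- start
  r <- round(start - step, 6)
  while (r >= floor_radius - 1e-9) {
    st <- probe(r)
    probes <- rbind(probes, data.frame(radius = r, status = st))
    if (st != "sat") break
    d_min <- r
    r <- round(r - step, 6)
  }
  list(radius = min(d_min + 0.5, start), d_min = d_min, probes = probes)
}

#' Re-run the assignment with user-fixed peaks
#'
#' Validates that each fix is a member of the peak's previous support set
#' (any other choice is unsatisfiable by construction), fixes the peaks in
#' the 2D list and re-runs the pipeline. Supports can only shrink.
#'
#' @param result a previous `assignment_result` (status "assigned").
#' @param fixes named character vector: names are peak ids, values methyl
#'   ids.
#' @param inputs the inputs used for the previous run (NOE lists are
#'   reused as supplied).
#' @return a new `assignment_result`.
#' @export
iterate_with_fixes <- function(result, fixes, inputs) {
  stopifnot(inherits(result, "assignment_result"),
            result$status == "assigned")
  peaks <- result$peaks2d
  for (pid in names(fixes)) {
    prev <- result$supports[[pid]]
    if (is.null(prev))
      stop("peak ", pid, " not present in the previous result")
    if (!(fixes[[pid]] %in% prev))
      stop("fix ", fixes[[pid]], " for peak ", pid,
           " is outside its previous support set {",
           paste(prev, collapse = ", "), "}")
    i <- match(as.integer(pid), peaks$peak_id)
    peaks$fixed_assignment[i] <- fixes[[pid]]
  }
  inputs$peaks2d <- peaks
  inputs$graph <- result$graph
  run_assignment(result$config, inputs)
}
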