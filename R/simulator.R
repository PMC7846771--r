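# Ground-truthed synthetic assignment problems.
#
# The generator emulates the experimental inputs end to end: a methyl
# "cloud" with protein-like packing and realistic geminal geometry, a data
# graph H sampled from the structure graph G at a target degree
# connectivity (the sparsity regime of real NOE data sets), and synthetic
# peak lists -- 2D reference shifts drawn from per-type methyl-region
# distributions, one upper- and one lower-diagonal NOESY cross-peak per H
# edge with bounded Gaussian jitter, diagonal peaks, and controllable
# forced spectral overlap. The planted mapping is recorded so recovery can
# be verified exactly.

compose_residues <- function(n_methyls, letters) {
  two <- intersect(letters, c("L", "V"))
  one <- intersect(letters, c("I", "A", "M"))
  if (length(one) == 0 && n_methyls %% 2 == 1)
    stop("cannot reach an odd methyl count with only Leu/Val in the scheme")
  types <- character(0)
  left <- n_methyls
  while (left > 0) {
    pool <- c(two[left >= 2], one)
    t <- sample(pool, 1)
    types <- c(types, t)
    left <- left - ifelse(t %in% c("L", "V"), 2, 1)
  }
  types
}

#' Generate a synthetic methyl cloud and its structure graph
#'
#' Methyl carbons are packed sequentially into a sphere at protein-like
#' density (default 0.003 methyls per cubic Angstrom, giving typical
#' nearest-neighbour distances of 4-7 Angstrom) with a minimum-separation
#' rejection rule; Leu/Val geminal partners are placed at the geminal
#' carbon-carbon distance around a shared parent atom. Protons are built at
#' ideal tetrahedral geometry. With `n_models > 1`, additional models
#' jitter the heavy atoms to emulate a conformational ensemble.
#'
#' @param n_methyls number of methyls (>= 2).
#' @param scheme labeling scheme code (default "ILV").
#' @param n_models ensemble size.
#' @param density methyls per cubic Angstrom.
#' @param min_sep minimum carbon-carbon separation in Angstrom.
#' @param geminal_cc geminal carbon-carbon distance in Angstrom.
#' @param model_jitter per-model heavy-atom jitter (sd, Angstrom).
#' @param short_radius,long_radius radii for the structure graph.
#' @param carbon_positions optional explicit carbon coordinate matrix
#'   (one row per methyl; overrides packing).
#' @param residue_types optional explicit residue letter sequence
#'   (one per residue; L/V contribute two methyls).
#' @param seed RNG seed (NULL = leave the RNG state alone).
#' @return list with `methyls` (a `methyl_set`), `graph` (a
#'   `structure_graph`), `sequence` and `carbons`.
#' @export
synth_structure <- function(n_methyls, scheme = "ILV", n_models = 1,
                            density = 0.003, min_sep = 4.0,
                            geminal_cc = 2.55, model_jitter = 0.25,
                            short_radius = 8, long_radius = 10,
                            carbon_positions = NULL, residue_types = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_methyls < 2) stop("need at least 2 methyls")
  sch <- parse_labeling_scheme(scheme)
  if (is.null(residue_types))
    residue_types <- compose_residues(n_methyls, sch$letters)
  res3 <- RES3[residue_types]
  per_res <- lapply(res3, scheme_methyls_for_residue, scheme = sch)
  n <- sum(vapply(per_res, nrow, integer(1)))
  if (n != n_methyls && is.null(residue_types))
    stop("internal error composing residues")

  radius <- (3 * n / (4 * pi * density))^(1 / 3)
  rand_in_sphere <- function() {
    repeat {
      p <- runif(3, -radius, radius)
      if (sum(p^2) <= radius^2) return(p)
    }
  }
  rand_unit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }

  # place carbons residue by residue
  tab <- list()
  carbons <- matrix(NA_real_, 0, 3)
  place_ok <- function(p, skip = 0) {
    nrow(carbons) == 0 ||
      all(sqrt(rowSums((carbons - matrix(p, nrow(carbons), 3,
                                         byrow = TRUE))^2)) >=
            c(rep(min_sep, nrow(carbons) - skip), rep(2.0, skip)))
  }
  for (r in seq_along(res3)) {
    mt <- per_res[[r]]
    if (!is.null(carbon_positions)) {
      pos <- carbon_positions[nrow(carbons) + seq_len(nrow(mt)), , drop = FALSE]
    } else if (nrow(mt) == 2) {
      pos <- NULL
      for (try in 1:2000) {
        c1 <- rand_in_sphere()
        c2 <- c1 + geminal_cc * rand_unit()
        if (place_ok(c1) && place_ok(c2)) { pos <- rbind(c1, c2); break }
      }
      if (is.null(pos)) stop("infeasible packing parameters (density/min_sep)")
    } else {
      pos <- NULL
      for (try in 1:2000) {
        c1 <- rand_in_sphere()
        if (place_ok(c1)) { pos <- rbind(c1); break }
      }
      if (is.null(pos)) stop("infeasible packing parameters (density/min_sep)")
    }
    for (k in seq_len(nrow(mt))) {
      tab[[length(tab) + 1]] <- data.frame(
        chain = "A", resno = r, res_type = res3[r],
        atom = mt$atom[k], stereo = mt$stereo[k], stringsAsFactors = FALSE)
    }
    carbons <- rbind(carbons, pos)
  }
  tab <- do.call(rbind, tab)
  tab$id <- methyl_label(tab$res_type, tab$resno, tab$atom)
  tab$geminal_id <- NA_character_
  for (i in seq_len(nrow(tab))) {
    sib <- which(tab$resno == tab$resno[i] & tab$atom != tab$atom[i] &
                 tab$res_type[i] %in% c("LEU", "VAL"))
    sib <- sib[tab$resno[sib] == tab$resno[i]]
    if (length(sib) == 1) tab$geminal_id[i] <- tab$id[sib]
  }

  # parent/gparent scaffold atoms for proton construction
  parents <- matrix(NA_real_, n, 3)
  gparents <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (done[i]) next
    sib <- match(tab$geminal_id[i], tab$id)
    if (!is.na(sib)) {
      mid <- (carbons[i, ] + carbons[sib, ]) / 2
      axis <- rand_unit()
      perp <- axis - sum(axis * (carbons[sib, ] - carbons[i, ])) *
        (carbons[sib, ] - carbons[i, ]) / sum((carbons[sib, ] - carbons[i, ])^2)
      perp <- perp / sqrt(sum(perp^2))
      h <- sqrt(max(1.53^2 - (geminal_cc / 2)^2, 0.25))
      hub <- mid + h * perp
      parents[i, ] <- hub; parents[sib, ] <- hub
      g <- hub + 1.5 * rand_unit()
      gparents[i, ] <- g; gparents[sib, ] <- g
      done[i] <- done[sib] <- TRUE
    } else {
      parents[i, ] <- carbons[i, ] + 1.52 * rand_unit()
      gparents[i, ] <- parents[i, ] + 1.5 * rand_unit()
      done[i] <- TRUE
    }
  }

  protons <- array(NA_real_, c(n_models, n, 3, 3))
  for (s in seq_len(n_models)) {
    jit <- if (s == 1) 0 else model_jitter
    for (i in seq_len(n)) {
      cpos <- carbons[i, ] + rnorm(3, 0, jit)
      ppos <- parents[i, ] + rnorm(3, 0, jit)
      gpos <- gparents[i, ] + rnorm(3, 0, jit)
      protons[s, i, , ] <- place_methyl_protons(cpos, ppos, gpos)
    }
  }

  ms <- new_methyl_set(tab[, c("id", "chain", "resno", "res_type", "atom",
                               "stereo", "geminal_id")], protons)
  g <- build_structure_graph(ms, short_radius = short_radius,
                             long_radius = long_radius)
  list(methyls = ms, graph = g,
       sequence = paste(residue_types, collapse = ""), carbons = carbons)
}

#' Sample a data graph from a structure graph at target connectivity
#'
#' Removes uniformly chosen edges from G until the degree connectivity
#' (2 x edges / nodes) falls inside the target range; the result H is the
#' NOE network a real experiment would observe at that sparsity.
#'
#' @param graph a `structure_graph`.
#' @param target two-element range of degree connectivity (default the
#'   experimentally characteristic 3.5-4.2, i.e. 1.75-2.1 observed NOEs
#'   per methyl).
#' @param seed RNG seed.
#' @return list with `edges` (the retained edge table, H) and
#'   `connectivity`.
#' @export
sample_data_graph <- function(graph, target = c(3.5, 4.2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(graph, "structure_graph"), length(target) == 2)
  lo <- min(target); hi <- max(target)
  n <- nrow(graph$methyls)
  edges <- graph$edges
  conn <- degree_connectivity(nrow(edges), n)
  if (conn < lo)
    stop(sprintf("structure graph connectivity %.2f is below the target range [%g, %g]",
                 conn, lo, hi))
  while (degree_connectivity(nrow(edges), n) > hi)
    edges <- edges[-sample.int(nrow(edges), 1), , drop = FALSE]
  conn <- degree_connectivity(nrow(edges), n)
  if (conn < lo)
    stop("target connectivity range too narrow to hit by single-edge removal")
  rownames(edges) <- NULL
  list(edges = edges, connectivity = conn)
}

#' Generate synthetic peak lists for a simulated instance
#'
#' Gives every methyl a (13C, 1H) reference shift drawn from its residue
#' type's methyl-region distribution; emits, for every edge of the data
#' graph H, one upper- and one lower-diagonal NOESY cross-peak with
#' bounded Gaussian jitter (short-range and geminal edges go to the
#' short-mixing list, all edges to the long-mixing list), plus diagonal
#' peaks; and optionally forces a fraction of 2D peak pairs to overlap
#' within the clustering tolerances.
#'
#' Jitter is clamped at two standard deviations, so with the default
#' tolerances (0.15 / 0.02 ppm) and jitter below ~0.07 ppm the planted
#' cluster and symmetry relations are guaranteed to survive, making the
#' planted assignment satisfiable by construction.
#'
#' Cross-peaks between methyls whose 13C shifts differ by less than
#' `diagonal_suppression` are not emitted: such peaks sit inside the
#' diagonal ridge of the spectrum and are not observable as separate
#' maxima by a peak picker (this mainly affects Leu/Val geminal pairs with
#' near-degenerate carbon shifts). The default margin guarantees that an
#' emitted cross-peak and its mirror are either both retained or both
#' removed by diagonal elimination at the matching tolerance.
#'
#' @param sim result of [synth_structure()].
#' @param h result of [sample_data_graph()].
#' @param jitter_ppm 13C jitter standard deviation in ppm (the 1H jitter is
#'   scaled down by the tolerance ratio 0.02/0.15).
#' @param overlap_rate fraction of 2D peaks moved within clustering
#'   tolerance of another same-type peak.
#' @param annotate_types,annotate_geminal,annotate_stereo which annotations
#'   to include in the 2D list.
#' @param include_diagonal emit diagonal NOE peaks.
#' @param diagonal_suppression minimum 13C shift difference (ppm) between
#'   two methyls for their cross-peaks to be observable off the diagonal;
#'   defaults to the diagonal-elimination tolerance plus the maximum
#'   mirror-asymmetry the clamped jitter can introduce.
#' @param seed RNG seed.
#' @return list with `peaks2d`, `noesy_short`, `noesy_long` and `truth`
#'   (list: `mapping` named peak_id -> methyl id, `shifts`, `h_edges`).
#' @export
synth_peak_lists <- function(sim, h, jitter_ppm = 0.02, overlap_rate = 0,
                             annotate_types = TRUE, annotate_geminal = TRUE,
                             annotate_stereo = FALSE, include_diagonal = TRUE,
                             diagonal_suppression = 0.15 + 4 * jitter_ppm,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- sim$graph$methyls
  n <- nrow(tab)
  # reference shifts: separated unless forced to overlap
  c_tol <- 0.15; h_tol <- 0.02
  cs <- numeric(n); hs <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      sh <- sample_methyl_shifts(1, res_type = tab$res_type[i],
                                 atom = tab$atom[i])
      if (i == 1 || !any(abs(cs[1:(i - 1)] - sh$c_shift) < 2.5 * c_tol &
                         abs(hs[1:(i - 1)] - sh$h_shift) < 2.5 * h_tol) ||
          try == 200) {
        cs[i] <- sh$c_shift; hs[i] <- sh$h_shift
        break
      }
    }
  }
  n_overlap <- round(overlap_rate * n)
  if (n_overlap > 0) {
    movable <- sample(n)
    moved <- 0
    for (i in movable) {
      same <- setdiff(which(RES1[tab$res_type] == RES1[tab$res_type[i]]), i)
      if (length(same) == 0) next
      j <- if (length(same) == 1) same else sample(same, 1)
      cs[i] <- cs[j] + runif(1, -0.5, 0.5) * c_tol
      hs[i] <- hs[j] + runif(1, -0.5, 0.5) * h_tol
      moved <- moved + 1
      if (moved >= n_overlap) break
    }
  }

  # 2D reference list under a random peak numbering
  perm <- sample(n)  # peak in row p corresponds to methyl perm[p]
  peaks <- data.frame(
    peak_id = seq_len(n),
    c_shift = cs[perm], h_shift = hs[perm],
    allowed_types = if (annotate_types) RES1[tab$res_type[perm]] else "any",
    stereo = if (annotate_stereo)
      ifelse(tab$stereo[perm] == "none", "unknown", tab$stereo[perm])
    else "unknown",
    geminal_partner = NA_integer_,
    fixed_assignment = NA_character_,
    stringsAsFactors = FALSE)
  if (annotate_geminal) {
    inv <- match(seq_len(n), perm)  # methyl index -> peak row
    sib <- match(tab$geminal_id, tab$id)
    peaks$geminal_partner <- ifelse(is.na(sib[perm]), NA_integer_,
                                    peaks$peak_id[inv[sib[perm]]])
  }
  peaks <- validate_peaks2d(peaks)

  jc <- function(k) pmin(pmax(rnorm(k, 0, jitter_ppm), -2 * jitter_ppm),
                         2 * jitter_ppm)
  jh_sd <- jitter_ppm * (h_tol / c_tol)
  jh <- function(k) pmin(pmax(rnorm(k, 0, jh_sd), -2 * jh_sd), 2 * jh_sd)

  he <- h$edges
  ia <- match(he$a, tab$id)
  ib <- match(he$b, tab$id)
  # cross-peaks inside the diagonal ridge are not observable
  observable <- abs(cs[ia] - cs[ib]) > diagonal_suppression
  he <- he[observable, , drop = FALSE]
  ia <- ia[observable]
  ib <- ib[observable]
  make_rows <- function(idx1, idx2) {
    k <- length(idx1)
    data.frame(c1 = cs[idx1] + jc(k), c2 = cs[idx2] + jc(k),
               h2 = hs[idx2] + jh(k))
  }
  long_rows <- rbind(make_rows(ia, ib), make_rows(ib, ia))
  long_truth <- data.frame(methyl_from = c(he$a, he$b),
                           methyl_to = c(he$b, he$a),
                           stringsAsFactors = FALSE)
  short_sel <- he$class %in% c("geminal", "short")
  short_rows <- rbind(make_rows(ia[short_sel], ib[short_sel]),
                      make_rows(ib[short_sel], ia[short_sel]))
  short_truth <- data.frame(
    methyl_from = c(he$a[short_sel], he$b[short_sel]),
    methyl_to = c(he$b[short_sel], he$a[short_sel]),
    stringsAsFactors = FALSE)
  if (include_diagonal) {
    diag_rows <- data.frame(c1 = cs + jc(n), c2 = cs + jc(n), h2 = hs + jh(n))
    long_rows <- rbind(long_rows, diag_rows)
    long_truth <- rbind(long_truth,
                        data.frame(methyl_from = tab$id, methyl_to = tab$id))
  }
  as_noe_list <- function(rows, mc) {
    structure(data.frame(noe_id = seq_len(nrow(rows)), c1 = rows$c1,
                         c2 = rows$c2, h2 = rows$h2,
                         h1 = rep(NA_real_, nrow(rows)),
                         mixing_class = rep(mc, nrow(rows)),
                         stringsAsFactors = FALSE),
              class = c("noe_list", "data.frame"))
  }
  mapping <- setNames(tab$id[perm], as.character(peaks$peak_id))
  list(peaks2d = peaks,
       noesy_short = as_noe_list(short_rows, "short"),
       noesy_long = as_noe_list(long_rows, "long"),
       truth = list(mapping = mapping,
                    shifts = data.frame(methyl = tab$id, c_shift = cs,
                                        h_shift = hs,
                                        stringsAsFactors = FALSE),
                    h_edges = he,
                    noe_truth = list(short = short_truth, long = long_truth)))
}

#' Generate a complete synthetic assignment instance
#'
#' Convenience wrapper: [synth_structure()] + [sample_data_graph()] +
#' [synth_peak_lists()] under a single seed.
#'
#' @param n_methyls number of methyls.
#' @param connectivity degree-connectivity target range for H.
#' @param overlap_rate forced 2D overlap fraction.
#' @param jitter_ppm NOE peak jitter (13C sd, ppm).
#' @param seed RNG seed (required, for reproducibility).
#' @param scheme,n_models passed to [synth_structure()].
#' @param annotate_types,annotate_geminal,annotate_stereo,include_diagonal
#'   passed to [synth_peak_lists()].
#' @return list with `structure` (synth_structure result), `h`, the peak
#'   lists and `truth` (see [synth_peak_lists()]).
#' @export
simulate_instance <- function(n_methyls, connectivity = c(3.5, 4.2),
                              overlap_rate = 0, jitter_ppm = 0.02, seed,
                              scheme = "ILV", n_models = 1,
                              annotate_types = TRUE, annotate_geminal = TRUE,
                              annotate_stereo = FALSE,
                              include_diagonal = TRUE) {
  set.seed(seed)
  sim <- synth_structure(n_methyls, scheme = scheme, n_models = n_models)
  h <- sample_data_graph(sim$graph, target = connectivity)
  pl <- synth_peak_lists(sim, h, jitter_ppm = jitter_ppm,
                         overlap_rate = overlap_rate,
                         annotate_types = annotate_types,
                         annotate_geminal = annotate_geminal,
                         annotate_stereo = annotate_stereo,
                         include_diagonal = include_diagonal)
  c(list(structure = sim, h = h, seed = seed), pl)
}
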