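# Labeled methyl groups: inventory from sequence + labeling scheme, and
# extraction (with proton coordinates) from a structure ensemble.

RES3 <- c(A = "ALA", I = "ILE", L = "LEU", V = "VAL", M = "MET")
RES1 <- setNames(names(RES3), RES3)

# methyl carbon atoms per residue type, with stereo class and the two
# heavy atoms needed to construct ideal methyl protons (parent, grandparent)
METHYL_ATOMS <- list(
  ALA = data.frame(atom = "CB",  stereo = "none", parent = "CA",  gparent = "N",
                   stringsAsFactors = FALSE),
  ILE = data.frame(atom = "CD1", stereo = "none", parent = "CG1", gparent = "CB",
                   stringsAsFactors = FALSE),
  LEU = data.frame(atom = c("CD1", "CD2"), stereo = c("proR", "proS"),
                   parent = "CG", gparent = "CB", stringsAsFactors = FALSE),
  VAL = data.frame(atom = c("CG1", "CG2"), stereo = c("proR", "proS"),
                   parent = "CB", gparent = "CA", stringsAsFactors = FALSE),
  MET = data.frame(atom = "CE",  stereo = "none", parent = "SD",  gparent = "CG",
                   stringsAsFactors = FALSE)
)

#' Parse a methyl labeling scheme code
#'
#' Scheme codes are a subset of the letters `A`, `I`, `L`, `V`, `M`
#' (e.g. `"ILV"`, `"AILV"`, `"MILV"`), optionally suffixed with `-proS`
#' for stereospecific proS labeling, in which case only the Leu delta-2 and
#' Val gamma-2 methyls are isotopically visible.
#'
#' @param scheme scheme code, e.g. `"ILV"` or `"AILV-proS"`.
#' @return list with `letters` (residue one-letter codes) and `proS` flag.
#' @export
parse_labeling_scheme <- function(scheme) {
  stopifnot(is.character(scheme), length(scheme) == 1)
  s <- gsub("[^A-Za-z]", "", scheme)
  proS <- grepl("PROS$", toupper(s))
  if (proS) s <- sub("(?i)PROS$", "", s, perl = TRUE)
  letters <- unique(strsplit(toupper(s), "")[[1]])
  bad <- setdiff(letters, names(RES3))
  if (length(bad) || length(letters) == 0)
    stop("unknown labeling scheme code: ", scheme)
  list(letters = letters, proS = proS)
}

# methyls implied by one residue under a scheme; NULL if none
scheme_methyls_for_residue <- function(res3, scheme) {
  if (!(res3 %in% names(RES1))) return(NULL)
  if (!(RES1[[res3]] %in% scheme$letters)) return(NULL)
  tab <- METHYL_ATOMS[[res3]]
  if (scheme$proS && res3 %in% c("LEU", "VAL"))
    tab <- tab[tab$stereo == "proS", , drop = FALSE]
  tab
}

methyl_label <- function(res3, resno, atom, chain = NULL, multi_chain = FALSE) {
  lab <- paste0(RES1[res3], resno, atom)
  if (multi_chain) paste0(chain, ".", lab) else lab
}

#' Read a PDB structure (single model or multi-model ensemble)
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the atom table plus a
#' per-model coordinate array. Chain identifiers and residue numbering are
#' taken verbatim from the file.
#'
#' @param path path to a PDB file.
#' @return object of class `structure_models`: list with `atoms`
#'   (data.frame: elety, resid, chain, resno) and `coords`
#'   (array `n_models x n_atoms x 3`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom[, c("elety", "resid", "chain", "resno")]
  atoms$chain[is.na(atoms$chain)] <- "A"
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(atoms)
  coords <- array(NA_real_, c(nrow(xyz), n_at, 3))
  for (s in seq_len(nrow(xyz)))
    coords[s, , ] <- matrix(xyz[s, ], ncol = 3, byrow = TRUE)
  structure(list(atoms = atoms, coords = coords), class = "structure_models")
}

# internal constructor used by the simulator and tests
new_structure_models <- function(atoms, coords) {
  structure(list(atoms = atoms, coords = coords), class = "structure_models")
}

# Ideal placement of an atom D from internal coordinates given three
# positioned atoms A-B-C (NeRF construction): |CD| = r, angle(B,C,D) = theta,
# torsion(A,B,C,D) = phi. Angles in radians.
place_atom <- function(a, b, c, r, theta, phi) {
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("collinear reference atoms in proton construction")
  n <- n / nn
  m1 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  c + cbind(bc, m1, n) %*% d2
}

# three methyl protons at ideal tetrahedral geometry, staggered about the
# carbon-parent axis (C-H 1.09 A, H-C-parent 109.47 deg)
place_methyl_protons <- function(c_pos, parent_pos, gparent_pos) {
  th <- 109.47 * pi / 180
  t(vapply(c(60, 180, 300) * pi / 180,
           function(phi) as.numeric(place_atom(gparent_pos, parent_pos, c_pos,
                                               1.09, th, phi)),
           numeric(3)))
}

#' Extract labeled methyl groups from a structure ensemble
#'
#' Identifies every methyl implied by the labeling scheme, verifies the
#' inventory against the construct sequence, and collects (or constructs)
#' the three methyl proton coordinates per structure model. When methyl
#' hydrogens are absent from the file they are built at ideal tetrahedral
#' geometry from the heavy-atom positions.
#'
#' Sequence numbering is matched to structure residue numbers verbatim:
#' position i of `sequence` corresponds to residue number i in the file.
#'
#' @param structure_models a `structure_models` object from
#'   [read_structure()].
#' @param labeling_scheme scheme code, see [parse_labeling_scheme()].
#' @param sequence construct sequence as a single-letter string.
#' @return object of class `methyl_set`: list with `table` (data.frame:
#'   id, chain, resno, res_type, atom, stereo, geminal_id) and `protons`
#'   (array `n_models x n_methyls x 3 protons x 3 xyz`).
#' @export
extract_methyls <- function(structure_models, labeling_scheme, sequence) {
  stopifnot(inherits(structure_models, "structure_models"))
  if (!is.character(sequence) || nchar(sequence[1]) == 0)
    stop("sequence must be a non-empty single-letter string")
  sequence <- toupper(sequence[1])
  scheme <- parse_labeling_scheme(labeling_scheme)

  atoms <- structure_models$atoms
  coords <- structure_models$coords
  n_models <- dim(coords)[1]
  chains <- unique(atoms$chain)
  multi <- length(chains) > 1

  seq_letters <- strsplit(sequence, "")[[1]]
  labeled_pos <- which(seq_letters %in% scheme$letters)

  # structure-side inventory
  rows <- list()
  res_key <- paste(atoms$chain, atoms$resno)
  for (ch in chains) {
    sel_ch <- atoms$chain == ch
    for (rn in unique(atoms$resno[sel_ch])) {
      sel <- sel_ch & atoms$resno == rn
      res3 <- atoms$resid[sel][1]
      # sequence/structure identity check
      if (rn >= 1 && rn <= length(seq_letters)) {
        sl <- seq_letters[rn]
        if (sl %in% names(RES3) && res3 %in% names(RES1) && RES3[[sl]] != res3)
          stop(sprintf("residue %d is %s in the structure but %s in the sequence",
                       rn, res3, RES3[[sl]]))
      }
      tab <- scheme_methyls_for_residue(res3, scheme)
      if (is.null(tab)) next
      if (rn >= 1 && rn <= length(seq_letters) &&
          !(seq_letters[rn] %in% scheme$letters)) next
      for (k in seq_len(nrow(tab))) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, resno = rn, res_type = res3,
          atom = tab$atom[k], stereo = tab$stereo[k],
          parent = tab$parent[k], gparent = tab$gparent[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no labeled methyls found in the structure")
  tab <- do.call(rbind, rows)
  tab$id <- methyl_label(tab$res_type, tab$resno, tab$atom, tab$chain, multi)

  # sequence-side check: every labeled methyl implied by the sequence must
  # exist in the structure (in at least one chain)
  missing <- character(0)
  for (p in labeled_pos) {
    res3 <- RES3[[seq_letters[p]]]
    want <- scheme_methyls_for_residue(res3, scheme)
    for (k in seq_len(nrow(want))) {
      hit <- tab$resno == p & tab$res_type == res3 & tab$atom == want$atom[k]
      if (!any(hit))
        missing <- c(missing, paste0(seq_letters[p], p, want$atom[k]))
    }
  }
  if (length(missing))
    stop("methyls implied by the sequence are missing from the structure: ",
         paste(unique(missing), collapse = ", "))

  # geminal sibling ids (the other methyl of the same Leu/Val residue)
  tab$geminal_id <- NA_character_
  lv <- tab$res_type %in% c("LEU", "VAL")
  for (i in which(lv)) {
    sib <- which(tab$chain == tab$chain[i] & tab$resno == tab$resno[i] &
                 tab$atom != tab$atom[i] & lv)
    if (length(sib) == 1) tab$geminal_id[i] <- tab$id[sib]
  }

  # proton coordinates
  n <- nrow(tab)
  protons <- array(NA_real_, c(n_models, n, 3, 3))
  atoms_key <- paste(atoms$chain, atoms$resno, atoms$elety)
  find_atom <- function(ch, rn, name) match(paste(ch, rn, name), atoms_key)
  hname <- function(atom) {
    # PDB v3 proton names: CD1 -> HD11 HD12 HD13, CB -> HB1..., CE -> HE1...
    stem <- sub("^C", "H", atom)
    paste0(stem, 1:3)
  }
  for (i in seq_len(n)) {
    hidx <- vapply(hname(tab$atom[i]),
                   function(nm) find_atom(tab$chain[i], tab$resno[i], nm),
                   integer(1))
    if (!any(is.na(hidx))) {
      for (s in seq_len(n_models))
        protons[s, i, , ] <- coords[s, hidx, , drop = FALSE]
    } else {
      ci <- find_atom(tab$chain[i], tab$resno[i], tab$atom[i])
      pi_ <- find_atom(tab$chain[i], tab$resno[i], tab$parent[i])
      gi <- find_atom(tab$chain[i], tab$resno[i], tab$gparent[i])
      if (any(is.na(c(ci, pi_, gi))))
        stop("cannot construct protons for ", tab$id[i],
             ": heavy atoms missing from the structure")
      for (s in seq_len(n_models))
        protons[s, i, , ] <- place_methyl_protons(coords[s, ci, ],
                                                  coords[s, pi_, ],
                                                  coords[s, gi, ])
    }
  }

  tab <- tab[, c("id", "chain", "resno", "res_type", "atom", "stereo",
                 "geminal_id")]
  rownames(tab) <- NULL
  structure(list(table = tab, protons = protons), class = "methyl_set")
}

#' @export
print.methyl_set <- function(x, ...) {
  cat(sprintf("<methyl_set> %d methyls, %d model(s)\n",
              nrow(x$table), dim(x$protons)[1]))
  print(table(x$table$res_type))
  invisible(x)
}

# internal constructor (simulator): table + protons array
new_methyl_set <- function(table, protons) {
  structure(list(table = table, protons = protons), class = "methyl_set")
}
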