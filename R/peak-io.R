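# Reading and writing peak lists.
#
# Native dialect: whitespace/tab-separated columns with a one-line header.
#   2D HMQC:  peak_id  c_shift  h_shift  types  stereo  geminal  fixed
#     types: residue letters ("LV"), "any" or "-"; stereo: proS/proR/-;
#     geminal: partner peak_id or "-"; fixed: methyl id like L45CD2 or "-".
#   3D NOESY: c1  c2  h2   (indirect 13C, direct 13C, direct 1H, in ppm)
#   4D NOESY: c1  h1  c2  h2
# Sparky dialect: NMRFAM-SPARKY peak-list export, first column an assignment
# label (ignored), then w1/w2(/w3) ppm columns; peaks numbered in file order.

MISSING_TOKENS <- c("-", ".", "NA", "")

#' Read a 2D HMQC reference peak list
#'
#' @param path file path.
#' @param dialect `"native"` (annotated, see package details) or `"sparky"`
#'   (NMRFAM-SPARKY export: label, w1 = 13C, w2 = 1H; no annotations).
#' @return data.frame of class `peak2d_list`: peak_id, c_shift, h_shift,
#'   allowed_types (letter string or "any"), stereo (proS/proR/unknown),
#'   geminal_partner (peak_id or NA), fixed_assignment (methyl id or NA).
#' @export
read_hmqc <- function(path, dialect = c("native", "sparky")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("HMQC peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("empty HMQC peak list: ", path)

  if (dialect == "sparky") {
    rows <- list()
    idx <- 0
    for (ln in keep) {
      f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(f) < 3) next
      w <- suppressWarnings(as.numeric(f[2:3]))
      if (any(is.na(w))) {
        if (ln == keep[1]) next  # header line
        stop("line ", ln, ": non-numeric ppm fields in ", path)
      }
      idx <- idx + 1
      rows[[idx]] <- data.frame(peak_id = idx, c_shift = w[1], h_shift = w[2],
                                allowed_types = "any", stereo = "unknown",
                                geminal_partner = NA_integer_,
                                fixed_assignment = NA_character_,
                                stringsAsFactors = FALSE)
    }
    return(validate_peaks2d(do.call(rbind, rows)))
  }

  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  body <- keep[-1]
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    ln <- body[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 3)
      stop("line ", ln, ": expected at least peak_id, c_shift, h_shift in ",
           path)
    length(f) <- 7
    id <- suppressWarnings(as.integer(f[1]))
    c_shift <- suppressWarnings(as.numeric(f[2]))
    h_shift <- suppressWarnings(as.numeric(f[3]))
    if (is.na(id) || is.na(c_shift) || is.na(h_shift))
      stop("line ", ln, ": malformed id or ppm fields in ", path)
    types <- f[4]
    if (is.na(types) || types %in% MISSING_TOKENS) types <- "any"
    if (tolower(types) != "any") {
      types <- toupper(types)
      if (!grepl("^[AILVM]+$", types))
        stop("line ", ln, ": malformed residue-type annotation '", f[4], "'")
      types <- paste(sort(unique(strsplit(types, "")[[1]])), collapse = "")
    } else types <- "any"
    st <- f[5]
    if (is.na(st) || st %in% MISSING_TOKENS) st <- "unknown"
    else if (tolower(st) %in% c("pros", "s")) st <- "proS"
    else if (tolower(st) %in% c("pror", "r")) st <- "proR"
    else stop("line ", ln, ": malformed stereo annotation '", f[5], "'")
    gp <- f[6]
    gp <- if (is.na(gp) || gp %in% MISSING_TOKENS) NA_integer_ else {
      g <- suppressWarnings(as.integer(gp))
      if (is.na(g)) stop("line ", ln, ": malformed geminal partner '", f[6], "'")
      g
    }
    fx <- f[7]
    fx <- if (is.na(fx) || fx %in% MISSING_TOKENS) NA_character_ else {
      if (!grepl("^[AILVM][0-9]+[A-Z0-9]+$", toupper(fx)))
        stop("line ", ln, ": malformed fixed assignment '", f[7], "'")
      toupper(fx)
    }
    rows[[k]] <- data.frame(peak_id = id, c_shift = c_shift, h_shift = h_shift,
                            allowed_types = types, stereo = st,
                            geminal_partner = gp, fixed_assignment = fx,
                            stringsAsFactors = FALSE)
  }
  validate_peaks2d(do.call(rbind, rows))
}

#' Validate a 2D reference peak table
#'
#' Checks unique peak ids, mutual geminal links, Leu/Val-compatibility of
#' geminal annotations and type-compatibility of fixed assignments.
#'
#' @param peaks data.frame with the `peak2d_list` columns.
#' @return the validated table, classed `peak2d_list`.
#' @export
validate_peaks2d <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (anyDuplicated(peaks$peak_id))
    stop("duplicate peak ids: ",
         paste(unique(peaks$peak_id[duplicated(peaks$peak_id)]), collapse = ", "))
  for (i in seq_len(nrow(peaks))) {
    gp <- peaks$geminal_partner[i]
    if (is.na(gp)) next
    j <- match(gp, peaks$peak_id)
    if (is.na(j))
      stop("peak ", peaks$peak_id[i], ": geminal partner ", gp, " does not exist")
    if (is.na(peaks$geminal_partner[j]) ||
        peaks$geminal_partner[j] != peaks$peak_id[i])
      stop("non-mutual geminal link between peaks ", peaks$peak_id[i],
           " and ", gp)
    tp <- peaks$allowed_types[i]
    if (tp != "any" && !grepl("^[LV]+$", tp))
      stop("peak ", peaks$peak_id[i],
           ": geminal annotation requires Leu/Val residue types, found '",
           tp, "'")
  }
  for (i in seq_len(nrow(peaks))) {
    fx <- peaks$fixed_assignment[i]
    if (is.na(fx)) next
    tp <- peaks$allowed_types[i]
    if (tp != "any" && !grepl(substr(fx, 1, 1), tp, fixed = TRUE))
      stop("peak ", peaks$peak_id[i], ": fixed assignment ", fx,
           " conflicts with allowed types '", tp, "'")
  }
  class(peaks) <- c("peak2d_list", "data.frame")
  peaks
}

#' Write a 2D reference peak list in the native dialect
#'
#' Round-trips exactly through [read_hmqc()].
#'
#' @param peaks a `peak2d_list`.
#' @param path output path.
#' @export
write_hmqc <- function(peaks, path) {
  out <- data.frame(
    peak_id = peaks$peak_id,
    c_shift = sprintf("%.6g", peaks$c_shift),
    h_shift = sprintf("%.6g", peaks$h_shift),
    types = peaks$allowed_types,
    stereo = ifelse(peaks$stereo == "unknown", "-", peaks$stereo),
    geminal = ifelse(is.na(peaks$geminal_partner), "-",
                     as.character(peaks$geminal_partner)),
    fixed = ifelse(is.na(peaks$fixed_assignment), "-",
                   peaks$fixed_assignment),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3D (or 4D) NOESY peak list
#'
#' 3D rows carry (c1, c2, h2): the indirect 13C, direct 13C and direct 1H
#' coordinates of one NOE cross-peak. 4D rows carry (c1, h1, c2, h2); the
#' extra indirect 1H is kept and used to sharpen symmetrization. Peaks are
#' numbered sequentially in file order.
#'
#' @param path file path.
#' @param mixing_class `"short"` (~50 ms) or `"long"` (~300 ms).
#' @param dialect `"native"` or `"sparky"`.
#' @param indirect_first logical; if `FALSE`, the first ppm column is the
#'   direct 13C dimension and columns are swapped on input.
#' @return data.frame of class `noe_list`: noe_id, c1, c2, h2, (h1,)
#'   mixing_class.
#' @export
read_noesy <- function(path, mixing_class = c("long", "short"),
                       dialect = c("native", "sparky"),
                       indirect_first = TRUE) {
  mixing_class <- match.arg(mixing_class)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("NOESY peak list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- list()
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (dialect == "sparky") f <- f[-1]
    w <- suppressWarnings(as.numeric(f))
    if (any(is.na(w)) || !(length(w) %in% c(3, 4))) {
      if (ln == keep[1]) next  # header
      stop("line ", ln, ": expected 3 (or 4) numeric ppm columns in ", path)
    }
    rows[[length(rows) + 1]] <- w
  }
  if (length(rows) == 0) {
    warning("empty NOESY peak list: ", path)
    return(structure(data.frame(noe_id = integer(0), c1 = numeric(0),
                                c2 = numeric(0), h2 = numeric(0),
                                h1 = numeric(0),
                                mixing_class = character(0)),
                     class = c("noe_list", "data.frame")))
  }
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1)
    stop("mixed 3- and 4-column rows in ", path)
  m <- do.call(rbind, rows)
  if (ncols == 3) {
    out <- data.frame(noe_id = seq_len(nrow(m)), c1 = m[, 1], c2 = m[, 2],
                      h2 = m[, 3], h1 = NA_real_,
                      mixing_class = mixing_class, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(noe_id = seq_len(nrow(m)), c1 = m[, 1], c2 = m[, 3],
                      h2 = m[, 4], h1 = m[, 2],
                      mixing_class = mixing_class, stringsAsFactors = FALSE)
  }
  if (!indirect_first) {
    tmp <- out$c1; out$c1 <- out$c2; out$c2 <- tmp
    if (ncols == 4) { tmp <- out$h1; out$h1 <- out$h2; out$h2 <- tmp }
  }
  structure(out, class = c("noe_list", "data.frame"))
}

#' Write a 3D NOESY peak list in the native dialect
#'
#' @param noes a `noe_list` (the 3D columns c1, c2, h2 are written).
#' @param path output path.
#' @export
write_noesy <- function(noes, path) {
  out <- data.frame(c1 = sprintf("%.6g", noes$c1),
                    c2 = sprintf("%.6g", noes$c2),
                    h2 = sprintf("%.6g", noes$h2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
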