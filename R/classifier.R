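# Chemical-shift residue-type classification.
#
# When no experimental residue-type information is available for a 2D
# reference peak, its (13C, 1H) position alone carries substantial type
# information: the methyl regions of Ala-beta, Ile-delta1, Leu-delta,
# Val-gamma and Met-epsilon overlap only partially. A frequency table over
# (13C, 1H) bins ranks residue types per bin; a peak is assigned the
# minimal set of types whose cumulative frequency reaches the threshold
# (99% by default).
#
# The packaged table is synthetic: it is materialised at load time from a
# small parameter file of per-methyl-type bivariate Gaussian shift
# statistics chosen to match the canonical methyl-region ranges, because
# assembling the real database statistics requires a download. The table
# object is user-replaceable: any table built by build_shift_table() from a
# parameter file of the same layout (or an empirical one with the same
# fields) slots in.

#' Build a binned chemical-shift frequency table
#'
#' Evaluates per-type shift densities on a (13C, 1H) grid and normalizes
#' within each bin, pre-computing for every bin the ranked residue-type
#' list and the minimal set reaching the cumulative-frequency threshold.
#'
#' @param params data.frame with columns `res_type`, `atom`, `c_mean`,
#'   `c_sd`, `h_mean`, `h_sd`, `weight` (relative abundance of the methyl
#'   type). Defaults to the packaged synthetic parameter file.
#' @param c_bin,h_bin bin widths in ppm (defaults 0.1 for 13C, 0.02 for 1H,
#'   matching the tolerance scales used elsewhere).
#' @param threshold cumulative frequency target for the minimal set.
#' @param pad grid extent in standard deviations beyond the parameter
#'   means.
#' @return object of class `shift_freq_table`.
#' @export
build_shift_table <- function(params = NULL, c_bin = 0.1, h_bin = 0.02,
                              threshold = 0.99, pad = 4) {
  if (is.null(params)) {
    path <- system.file("extdata", "methyl_shift_params_synthetic.csv",
                        package = "methylsat")
    params <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("res_type", "atom", "c_mean", "c_sd", "h_mean", "h_sd", "weight")
  stopifnot(all(need %in% names(params)))
  c_lo <- min(params$c_mean - pad * params$c_sd)
  c_hi <- max(params$c_mean + pad * params$c_sd)
  h_lo <- min(params$h_mean - pad * params$h_sd)
  h_hi <- max(params$h_mean + pad * params$h_sd)
  c_breaks <- seq(floor(c_lo / c_bin) * c_bin, ceiling(c_hi / c_bin) * c_bin,
                  by = c_bin)
  h_breaks <- seq(floor(h_lo / h_bin) * h_bin, ceiling(h_hi / h_bin) * h_bin,
                  by = h_bin)
  c_mid <- head(c_breaks, -1) + c_bin / 2
  h_mid <- head(h_breaks, -1) + h_bin / 2
  nc <- length(c_mid); nh <- length(h_mid)

  types <- unique(params$res_type)
  # density of each residue type per bin: sum over its methyl atoms of
  # weight * N(c) * N(h), evaluated at bin centers
  dens <- array(0, c(nc, nh, length(types)), dimnames = list(NULL, NULL, types))
  for (r in seq_len(nrow(params))) {
    dc <- dnorm(c_mid, params$c_mean[r], params$c_sd[r])
    dh <- dnorm(h_mid, params$h_mean[r], params$h_sd[r])
    t <- params$res_type[r]
    dens[, , t] <- dens[, , t] + params$weight[r] * outer(dc, dh)
  }
  tot <- apply(dens, c(1, 2), sum)
  # minimal >= threshold set per bin, ranked by decreasing frequency
  sets <- matrix(NA_character_, nc, nh)
  freq <- array(NA_real_, c(nc, nh, length(types)),
                dimnames = list(NULL, NULL, types))
  for (i in seq_len(nc)) for (j in seq_len(nh)) {
    if (tot[i, j] < .Machine$double.xmin * 1e10) next  # empty bin
    f <- dens[i, j, ] / tot[i, j]
    freq[i, j, ] <- f
    o <- order(f, decreasing = TRUE)
    cum <- cumsum(f[o])
    k <- which(cum >= threshold)[1]
    sets[i, j] <- paste(RES1[RES3_LONG(types[o[seq_len(k)]])], collapse = "")
  }
  structure(list(c_breaks = c_breaks, h_breaks = h_breaks,
                 sets = sets, freq = freq, dens = dens,
                 threshold = threshold, params = params),
            class = "shift_freq_table")
}

# residue types in the params file are one- or three-letter; normalize
RES3_LONG <- function(x) {
  up <- toupper(x)
  ifelse(up %in% names(RES1), up, RES3[up])
}

#' @export
print.shift_freq_table <- function(x, ...) {
  cat(sprintf("<shift_freq_table> %d x %d bins, threshold %.2f, types: %s\n",
              length(x$c_breaks) - 1, length(x$h_breaks) - 1, x$threshold,
              paste(dimnames(x$freq)[[3]], collapse = ", ")))
  invisible(x)
}

#' Predict allowed residue types from chemical shifts
#'
#' Returns, for each (13C, 1H) position, the minimal set of residue types
#' whose cumulative bin frequency reaches the table's threshold, as a
#' letter string usable directly as a 2D peak `allowed_types` annotation.
#' Positions outside the table's coverage (or in bins with no support)
#' return `"any"` with a warning.
#'
#' @param c_shift,h_shift numeric vectors of shifts in ppm (recycled).
#' @param table a `shift_freq_table`; default: the packaged synthetic
#'   table.
#' @param threshold optional override of the table's cumulative threshold
#'   (lowering it can only shrink the returned sets).
#' @return character vector of type-letter strings (e.g. `"LV"`) or
#'   `"any"`.
#' @export
classify_residue_type <- function(c_shift, h_shift, table = NULL,
                                  threshold = NULL) {
  if (is.null(table)) table <- packaged_shift_table()
  n <- max(length(c_shift), length(h_shift))
  c_shift <- rep_len(c_shift, n)
  h_shift <- rep_len(h_shift, n)
  ci <- findInterval(c_shift, table$c_breaks,
                     rightmost.closed = TRUE, all.inside = FALSE)
  hi <- findInterval(h_shift, table$h_breaks,
                     rightmost.closed = TRUE, all.inside = FALSE)
  nc <- length(table$c_breaks) - 1
  nh <- length(table$h_breaks) - 1
  out <- character(n)
  warned <- FALSE
  for (k in seq_len(n)) {
    if (ci[k] < 1 || ci[k] > nc || hi[k] < 1 || hi[k] > nh ||
        is.na(table$sets[ci[k], hi[k]])) {
      out[k] <- "any"
      warned <- TRUE
      next
    }
    if (is.null(threshold)) {
      out[k] <- table$sets[ci[k], hi[k]]
    } else {
      f <- table$freq[ci[k], hi[k], ]
      o <- order(f, decreasing = TRUE)
      m <- which(cumsum(f[o]) >= threshold)[1]
      types <- dimnames(table$freq)[[3]][o[seq_len(m)]]
      out[k] <- paste(RES1[RES3_LONG(types)], collapse = "")
    }
  }
  if (warned)
    warning("some shifts fall outside the frequency table's coverage; ",
            "returning \"any\" for those peaks")
  out
}

# lazily built packaged table, cached for the session
.shift_table_cache <- new.env(parent = emptyenv())
packaged_shift_table <- function() {
  if (is.null(.shift_table_cache$tab))
    .shift_table_cache$tab <- build_shift_table()
  .shift_table_cache$tab
}

#' Sample methyl chemical shifts from a frequency table's model
#'
#' Draws (residue type, atom, 13C, 1H) tuples from the per-type Gaussian
#' parameters behind a table. Used by the simulator (so synthetic peak
#' positions live in realistic methyl regions) and by the classifier's
#' self-consistency checks.
#'
#' @param n number of draws.
#' @param table a `shift_freq_table` (default: packaged).
#' @param res_type optional three-letter residue type to condition on.
#' @param atom optional atom name to condition on.
#' @return data.frame: res_type, atom, c_shift, h_shift.
#' @export
sample_methyl_shifts <- function(n, table = NULL, res_type = NULL,
                                 atom = NULL) {
  if (is.null(table)) table <- packaged_shift_table()
  p <- table$params
  if (!is.null(res_type)) p <- p[RES3_LONG(p$res_type) %in% res_type, ,
                                 drop = FALSE]
  if (!is.null(atom)) p <- p[p$atom %in% atom, , drop = FALSE]
  stopifnot(nrow(p) > 0)
  r <- sample.int(nrow(p), n, replace = TRUE, prob = p$weight)
  data.frame(res_type = RES3_LONG(p$res_type[r]), atom = p$atom[r],
             c_shift = rnorm(n, p$c_mean[r], p$c_sd[r]),
             h_shift = rnorm(n, p$h_mean[r], p$h_sd[r]),
             stringsAsFactors = FALSE)
}
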