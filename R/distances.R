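# Effective inter-methyl distances.
#
# A methyl group carries three equivalent protons rotating rapidly about the
# symmetry axis; the NOE between two methyls reports on all nine interproton
# distances at once. Two aggregates of the nine distances are in common use:
# the plain r^-6 sum (appropriate for absolute NOE intensity bounds) and the
# multiplicity-corrected average, which divides by the number of proton
# pairs and therefore stays within the range of the observed interproton
# distances. Graph construction uses the averaged form.

#' Multiplicity-corrected effective distance between two methyl groups
#'
#' Computes `((1/9) * sum_ij d(p_i, q_j)^-6)^(-1/6)` over the nine proton
#' pairs of two methyl groups: the r^-6 average of all interproton
#' distances. The result is symmetric in its arguments and always lies
#' between the minimum and maximum pairwise proton distance.
#'
#' @param protons_p,protons_q numeric 3x3 matrices; one proton position
#'   (x, y, z in Angstrom) per row.
#' @return effective distance in Angstrom.
#' @seealso [r6_sum_distance()], [r6_average_distance()]
#' @export
#' @examples
#' p <- matrix(rnorm(9), 3, 3)
#' q <- matrix(rnorm(9) + 5, 3, 3)
#' effective_distance(p, q)
effective_distance <- function(protons_p, protons_q) {
  protons_p <- as.matrix(protons_p)
  protons_q <- as.matrix(protons_q)
  stopifnot(identical(dim(protons_p), c(3L, 3L)),
            identical(dim(protons_q), c(3L, 3L)),
            all(is.finite(protons_p)), all(is.finite(protons_q)))
  d2 <- outer(seq_len(3), seq_len(3),
              Vectorize(function(i, j) sum((protons_p[i, ] - protons_q[j, ])^2)))
  if (any(d2 == 0))
    stop("degenerate geometry: coincident protons across the two methyl groups")
  mean(d2^-3)^(-1 / 6)
}

#' r^-6 summed distance
#'
#' The conventional r^-6 summation `(sum_i d_i^-6)^(-1/6)` over a set of
#' distances. Always less than or equal to the multiplicity-corrected
#' average of the same distances; kept for documented comparison, not used
#' in graph construction.
#'
#' @param distances positive distances in Angstrom.
#' @return summed effective distance in Angstrom.
#' @export
#' @examples
#' r6_sum_distance(c(4, 5.5, 7))      # 3.9 when rounded to one decimal
r6_sum_distance <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) stop("empty distance list")
  if (any(!is.finite(distances) | distances <= 0))
    stop("all distances must be finite and positive")
  sum(distances^-6)^(-1 / 6)
}

#' r^-6 averaged distance
#'
#' The multiplicity-corrected form `((1/n) * sum_i d_i^-6)^(-1/6)` over a
#' distance multiset. For the nine proton-pair distances of two methyls this
#' equals [effective_distance()].
#'
#' @inheritParams r6_sum_distance
#' @return averaged effective distance in Angstrom.
#' @export
#' @examples
#' r6_average_distance(c(4, 5.5, 7))  # 4.7 when rounded to one decimal
r6_average_distance <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) stop("empty distance list")
  if (any(!is.finite(distances) | distances <= 0))
    stop("all distances must be finite and positive")
  mean(distances^-6)^(-1 / 6)
}

#' Ensemble-minimum effective distance
#'
#' Minimum of the per-model effective distances over a conformational
#' ensemble. Sampling alternative side-chain conformations and taking the
#' minimum makes the structure graph tolerant of rotamer variation: a pair
#' of methyls is considered close if it is close in any supplied model.
#'
#' @param models_p,models_q lists of 3x3 proton-coordinate matrices, one per
#'   model, in matching model order.
#' @return minimum effective distance in Angstrom.
#' @export
ensemble_min_distance <- function(models_p, models_q) {
  if (length(models_p) == 0 || length(models_p) != length(models_q))
    stop("need the same positive number of models for both methyls")
  min(vapply(seq_along(models_p),
             function(s) effective_distance(models_p[[s]], models_q[[s]]),
             numeric(1)))
}
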