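#' Control-derived ecological niche range
#'
#' The native functional niche of the soil is summarised per substrate by
#' the minimum, mean and maximum response observed across the control
#' replicates. Treated samples are later decomposed against this range.
#'
#' @param control_profiles Profile matrix of the control replicates
#'   (rows = replicates), or a list of `sample_profile` objects.
#' @return A `niche_range` data frame with columns `code`, `lower`,
#'   `center`, `upper` and attribute `n_control`.
#' @export
niche_range <- function(control_profiles) {
  if (is.list(control_profiles) && !is.data.frame(control_profiles)) {
    control_profiles <- profile_matrix(control_profiles)
  }
  if (nrow(control_profiles) < 2) {
    stop("a niche range needs at least 2 control replicates, found ",
         nrow(control_profiles))
  }
  rng <- data.frame(code = colnames(control_profiles),
                    lower = apply(control_profiles, 2, min),
                    center = colMeans(control_profiles),
                    upper = apply(control_profiles, 2, max),
                    row.names = NULL)
  attr(rng, "n_control") <- nrow(control_profiles)
  class(rng) <- c("niche_range", "data.frame")
  rng
}

#' Decompose a profile into the four complementary niche segments
#'
#' For every substrate the deviation of the observed response `x` from the
#' control mean (`center`) is split at the control limits:
#' * `x >= center`: **intensification** is the part of the increase inside
#'   the niche (`min(x, upper) - center`) and **expansion** the part beyond
#'   the control maximum (`max(0, x - upper)`);
#' * `x < center`: **narrowing** is the decrease inside the niche
#'   (`center - max(x, lower)`) and **contraction** the part below the
#'   control minimum (`max(0, lower - x)`).
#'
#' All four components are non-negative, at most one side (increase or
#' decrease) is non-zero per substrate, and
#' `intensification + expansion - narrowing - contraction = x - center`
#' holds exactly.
#'
#' @param profiles Profile matrix (samples x substrates) or a single named
#'   profile vector.
#' @param range A [niche_range()] over the same substrates.
#' @return A `niche_decomposition`: list of four matrices
#'   (`intensification`, `expansion`, `narrowing`, `contraction`), each
#'   samples x substrates.
#' @export
niche_decompose <- function(profiles, range) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("sample", names(profiles)))
  }
  if (!setequal(colnames(profiles), range$code)) {
    stop("profile and niche range cover different substrate sets")
  }
  profiles <- profiles[, range$code, drop = FALSE]
  center <- rep(range$center, each = nrow(profiles))
  lower <- rep(range$lower, each = nrow(profiles))
  upper <- rep(range$upper, each = nrow(profiles))
  x <- profiles
  up <- x >= center
  shape <- function(v) {
    dim(v) <- dim(x); dimnames(v) <- dimnames(x); v
  }
  out <- list(
    intensification = shape(ifelse(up, pmin(x, upper) - center, 0)),
    expansion       = shape(ifelse(up, pmax(0, x - upper), 0)),
    narrowing       = shape(ifelse(up, 0, center - pmax(x, lower))),
    contraction     = shape(ifelse(up, 0, pmax(0, lower - x)))
  )
  structure(out, class = "niche_decomposition", range = range)
}

#' Names of the four niche segments
#' @return `c("intensification", "expansion", "narrowing", "contraction")`
#' @export
segment_names <- function() {
  c("intensification", "expansion", "narrowing", "contraction")
}

#' Synthetic segment indices
#'
#' Each segment's per-sample index is its summed OD expressed as a percent
#' of that sample's own total activity `S`:
#' `I_seg = 100 * sum_s(seg_s) / S`.
#'
#' @param decomp A [niche_decompose()] result.
#' @param profiles The profile matrix the decomposition was computed from.
#' @return Data frame with one row per sample: `sample_id`, `total` and the
#'   four index columns (percent).
#' @export
segment_indices <- function(decomp, profiles) {
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("sample", names(profiles)))
  }
  S <- rowSums(profiles)
  if (any(S <= 0)) {
    stop("segment indices undefined for zero-total sample(s): ",
         paste(rownames(profiles)[S <= 0], collapse = ", "))
  }
  out <- data.frame(sample_id = rownames(profiles), total = unname(S),
                    row.names = NULL)
  for (seg in segment_names()) {
    out[[seg]] <- unname(segment_index(rowSums(decomp[[seg]]), S))
  }
  out
}

#' Percent index of one niche segment
#'
#' `100 * segment_sum / total`: the building block of the four synthetic
#' indices, usable directly on treatment-level summary values (e.g. summed
#' guild means and a mean total activity).
#'
#' @param segment_sum Summed segment OD (scalar or vector).
#' @param total Total activity `S` of the same sample(s) (OD sum).
#' @return Percent value(s).
#' @export
segment_index <- function(segment_sum, total) {
  if (any(total <= 0)) stop("total activity must be positive")
  100 * segment_sum / total
}

#' Functional alteration
#'
#' Signed percent change of a community's total substrate activity relative
#' to the control mean total: `FA = 100 * (S - S_c) / S_c`. Positive values
#' indicate an oversized functional community, negative values a reduced
#' one.
#'
#' @param total Total activity `S` of the sample(s), or a treatment mean
#'   total (scalar or vector).
#' @param control_total Control mean total activity `S_c` (e.g.
#'   `sum(range$center)` for a [niche_range()]).
#' @return Signed percent value(s).
#' @examples
#' functional_alteration(45.4, 50.7)   # about -10.45
#' @export
functional_alteration <- function(total, control_total) {
  if (length(control_total) != 1 || control_total <= 0) {
    stop("control mean total activity must be a single positive number")
  }
  100 * (total - control_total) / control_total
}

#' Shared profile with the control community
#'
#' The part of a sample's activity that the control community also
#' expresses: per substrate, `min(x_s, center_s)`. The matrix of shared
#' profiles over all samples is the input of the common-microbiome
#' ordination.
#'
#' @param profiles Profile matrix or single named profile vector.
#' @param range A [niche_range()].
#' @return Matrix (or vector) of shared responses, same shape as the input.
#' @export
common_with_control <- function(profiles, range) {
  vec <- is.null(dim(profiles))
  if (vec) {
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("sample", names(profiles)))
  }
  if (!setequal(colnames(profiles), range$code)) {
    stop("profile and niche range cover different substrate sets")
  }
  profiles <- profiles[, range$code, drop = FALSE]
  shared <- pmin(profiles, rep(range$center, each = nrow(profiles)))
  if (vec) shared[1, ] else shared
}
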