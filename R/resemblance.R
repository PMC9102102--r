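#' Within-community functional resemblance
#'
#' Pairwise Czekanowski percentage similarity between the replicates of one
#' treatment: `PS(a, b) = 200 * sum_s min(a_s, b_s) / (sum_s a_s + sum_s
#' b_s)`. Each replicate's value is the mean over its pairs; the treatment
#' is summarised as mean and standard error over replicates.
#'
#' @param profiles Profile matrix of one treatment's replicates.
#' @return List with `values` (per-replicate %), `mean` and `se`.
#' @examples
#' m <- rbind(a = c(2, 2), b = c(2, 0))
#' within_resemblance(m)$values   # both 200*2/6
#' @export
within_resemblance <- function(profiles) {
  n <- nrow(profiles)
  if (is.null(n) || n < 2) stop("within-resemblance needs at least 2 replicates")
  ps <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ps[i, j] <- ps[j, i] <- percentage_similarity(profiles[i, ], profiles[j, ])
    }
  }
  vals <- rowMeans(ps, na.rm = TRUE)
  names(vals) <- rownames(profiles)
  list(values = vals, mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)))
}

#' @rdname within_resemblance
#' @param a,b Two profiles over the same substrates.
#' @export
percentage_similarity <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom <= 0) stop("percentage similarity undefined for two empty profiles")
  200 * sum(pmin(a, b)) / denom
}

#' Between-community functional resemblance
#'
#' For a replicate `r` of treatment `t`, its coverage in another treatment
#' `u` is the percent of `r`'s activity also expressed by `u`'s mean
#' profile: `100 * sum_s min(x_rs, m_us) / sum_s x_rs`. The replicate's
#' between-community value averages its coverage over all other treatments
#' (`u != t`), and each treatment is reported as mean and standard error
#' over its replicates.
#'
#' @param profiles Profile matrix over all samples.
#' @param design Design data frame.
#' @param include_control Should the control treatment count among the
#'   "other" communities? Default `TRUE`.
#' @param control Control treatment label (only needed when
#'   `include_control = FALSE`).
#' @return Data frame `treatment`, `mean`, `se`, with the per-sample values
#'   in attribute `per_sample`.
#' @export
between_resemblance <- function(profiles, design, include_control = TRUE,
                                control = NULL) {
  design <- validate_design(design)
  if (length(unique(design$treatment)) < 2) {
    stop("between-resemblance needs at least 2 treatments")
  }
  if (!include_control && is.null(control)) {
    stop("control label required when include_control = FALSE")
  }
  profiles <- profiles[design$sample_id, , drop = FALSE]
  trts <- unique(design$treatment)
  mean_profiles <- vapply(trts, function(u) {
    colMeans(profiles[design$treatment == u, , drop = FALSE])
  }, numeric(ncol(profiles)))
  totals <- rowSums(profiles)
  keep <- totals > 0
  if (any(!keep)) {
    warning("skipping zero-total sample(s): ",
            paste(design$sample_id[!keep], collapse = ", "))
  }
  per_sample <- vapply(which(keep), function(i) {
    t_i <- design$treatment[i]
    others <- setdiff(trts, t_i)
    if (!include_control) others <- setdiff(others, control)
    cov_u <- vapply(others, function(u) {
      100 * sum(pmin(profiles[i, ], mean_profiles[, u])) / totals[i]
    }, numeric(1))
    mean(cov_u)
  }, numeric(1))
  names(per_sample) <- design$sample_id[keep]
  trt_kept <- design$treatment[keep]
  out <- data.frame(
    treatment = trts,
    mean = vapply(trts, function(t) mean(per_sample[trt_kept == t]), numeric(1)),
    se = vapply(trts, function(t) {
      v <- per_sample[trt_kept == t]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL)
  attr(out, "per_sample") <- per_sample
  out
}
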