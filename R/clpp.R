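#' Conventional CLPP metrics
#'
#' Per-sample summaries of a blank-corrected substrate profile: total
#' activity `S` (the OD sum over the 31 substrates), average well colour
#' development (`AWCD = S/31`), Shannon diversity `H = -sum p_s log p_s` in
#' nats, and Gini-Simpson diversity `D = 1 - sum p_s^2`, where
#' `p_s = x_s / S` are substrate proportions and zero-response substrates
#' contribute nothing (`0 * log 0 := 0`).
#'
#' @param x Numeric vector of 31 non-negative substrate responses (a profile
#'   matrix row, or `sample_profile$x`).
#' @return A single number.
#' @examples
#' x <- rep(1.35, 31)
#' clpp_awcd(x)      # 1.35
#' clpp_shannon(x)   # log(31)
#' clpp_simpson(x)   # 1 - 1/31
#' @name clpp_metrics
NULL

#' @rdname clpp_metrics
#' @export
clpp_awcd <- function(x) {
  check_profile(x)
  mean(x)
}

#' @rdname clpp_metrics
#' @export
clpp_shannon <- function(x) {
  check_profile(x)
  S <- sum(x)
  if (S <= 0) stop("diversity undefined for an all-zero profile")
  p <- x[x > 0] / S
  -sum(p * log(p))
}

#' @rdname clpp_metrics
#' @export
clpp_simpson <- function(x) {
  check_profile(x)
  S <- sum(x)
  if (S <= 0) stop("diversity undefined for an all-zero profile")
  p <- x / S
  1 - sum(p^2)
}

check_profile <- function(x) {
  if (!is.numeric(x)) stop("profile must be numeric")
  if (any(x < 0)) stop("profile responses must be non-negative")
  invisible(x)
}

#' Treatment-level summary of conventional CLPP metrics
#'
#' Computes `S`, AWCD, Shannon and Simpson per sample, then the arithmetic
#' mean and standard error (sd/sqrt(n)) per treatment, with LSD compact
#' letters attached per metric (see [lsd_letters()]).
#'
#' @param profiles Profile matrix, samples x substrates.
#' @param design Design data frame (`sample_id`, `treatment`, `replicate`).
#' @param alpha Significance level for the letter display.
#' @return A data frame with one row per treatment and, for each metric,
#'   `<metric>_mean`, `<metric>_se` and `<metric>_letter` columns, plus the
#'   omnibus ANOVA `F` and `p` per metric as attributes `anova`.
#' @export
clpp_summary <- function(profiles, design, alpha = 0.05) {
  design <- validate_design(design)
  profiles <- profiles[design$sample_id, , drop = FALSE]
  per_sample <- data.frame(
    sample_id = design$sample_id,
    treatment = design$treatment,
    sum = rowSums(profiles),
    awcd = rowMeans(profiles),
    shannon = apply(profiles, 1, clpp_shannon),
    simpson = apply(profiles, 1, clpp_simpson)
  )
  summarize_metrics(per_sample, c("sum", "awcd", "shannon", "simpson"), alpha)
}

# Shared mean +- s.e. + letters summariser over a per-sample table with a
# 'treatment' column.
summarize_metrics <- function(per_sample, metrics, alpha = 0.05) {
  trt <- unique(per_sample$treatment)
  out <- data.frame(treatment = trt)
  anova_rows <- list()
  for (m in metrics) {
    vals <- split(per_sample[[m]], per_sample$treatment)[trt]
    n <- lengths(vals)
    mu <- vapply(vals, mean, numeric(1))
    se <- vapply(vals, function(v) {
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    }, numeric(1))
    if (any(n < 2)) {
      warning("treatment(s) with a single replicate: s.e. reported as NA for ",
              m)
    }
    out[[paste0(m, "_mean")]] <- unname(mu)
    out[[paste0(m, "_se")]] <- unname(se)
    if (length(vals) >= 2 && all(n >= 2)) {
      aov_res <- one_way_anova(vals)
      letters <- lsd_letters(vals, alpha = alpha)
      out[[paste0(m, "_letter")]] <- unname(letters[trt])
      anova_rows[[m]] <- data.frame(metric = m, F = aov_res$F, p = aov_res$p,
                                    df_between = aov_res$df_between,
                                    df_within = aov_res$df_within)
    } else {
      out[[paste0(m, "_letter")]] <- NA_character_
    }
  }
  attr(out, "anova") <- do.call(rbind, anova_rows)
  out
}
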