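#' One-way fixed-effects ANOVA
#'
#' Classical between/within variance decomposition over `k` groups, fitted
#' through [stats::lm()]. Degenerate inputs are resolved by convention:
#' zero within-group variance with equal means gives `F = 0, p = 1`; zero
#' within-group variance with unequal means gives `F = Inf, p = 0`.
#'
#' @param values Named list of numeric vectors, one per group (each of
#'   length >= 2), or an unnamed list.
#' @return List with `F`, `p`, `df_between`, `df_within`, `mse` (the pooled
#'   within-group mean square) and `means`/`n` per group.
#' @export
one_way_anova <- function(values) {
  values <- as_group_list(values)
  k <- length(values)
  if (k < 2) stop("ANOVA needs at least 2 groups")
  if (any(lengths(values) < 2)) stop("every group needs at least 2 values")
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  tab <- withCallingHandlers(
    stats::anova(stats::lm(y ~ g)),
    warning = function(w) {
      # zero residual variance is resolved by convention below
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  mse <- tab[["Mean Sq"]][2]
  if (is.nan(Fv) || is.na(Fv)) {     # 0/0: all values identical
    Fv <- 0; p <- 1
  } else if (is.infinite(Fv)) {
    p <- 0
  }
  list(F = Fv, p = p,
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       mse = mse,
       means = vapply(values, mean, numeric(1)),
       n = lengths(values))
}

as_group_list <- function(values) {
  stopifnot(is.list(values))
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    names(values) <- paste0("g", seq_along(values))
  }
  values
}

#' LSD compact letter display
#'
#' Pairwise least-significant-difference tests on the pooled ANOVA mean
#' square: groups `i` and `j` differ when `|m_i - m_j| > t(1 - alpha/2,
#' df_within) * sqrt(MSE * (1/n_i + 1/n_j))`. Letters are assigned with the
#' insert-and-absorb algorithm on groups ordered by descending mean, so two
#' groups share a letter exactly when their pairwise test is
#' non-significant. Unprotected by default (letters are assigned whether or
#' not the omnibus F test is significant); set `protect = TRUE` to collapse
#' all groups to `"a"` when the omnibus p-value exceeds `alpha`.
#'
#' @param values Named list of numeric vectors, one per group.
#' @param alpha Significance level (default 0.05).
#' @param protect Gate the letters on the omnibus ANOVA? Default `FALSE`.
#' @return Named character vector of letter strings, in input group order.
#' @export
lsd_letters <- function(values, alpha = 0.05, protect = FALSE) {
  values <- as_group_list(values)
  aov_res <- one_way_anova(values)
  k <- length(values)
  if (protect && aov_res$p >= alpha) {
    return(stats::setNames(rep("a", k), names(values)))
  }
  sig <- lsd_significant(aov_res, alpha)
  letters_from_significance(sig, aov_res$means)
}

# Pairwise LSD significance matrix (TRUE = significantly different).
lsd_significant <- function(aov_res, alpha = 0.05) {
  m <- aov_res$means
  n <- aov_res$n
  k <- length(m)
  tcrit <- stats::qt(1 - alpha / 2, aov_res$df_within)
  sig <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      lsd <- tcrit * sqrt(aov_res$mse * (1 / n[i] + 1 / n[j]))
      different <- if (aov_res$mse == 0) m[i] != m[j]
                   else abs(m[i] - m[j]) > lsd
      sig[i, j] <- sig[j, i] <- different
    }
  }
  sig
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix over groups; letters are assigned on groups ordered by descending
# mean and returned in the matrix's group order.
letters_from_significance <- function(sig, means) {
  k <- nrow(sig)
  ord <- order(-means)
  cols <- list(rep(TRUE, k))           # start: everyone shares one letter
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- ord[i]; b <- ord[j]
      if (!sig[a, b]) next
      for (ci in rev(seq_along(cols))) {
        col <- cols[[ci]]
        if (col[a] && col[b]) {        # split the column on this pair
          c1 <- col; c1[a] <- FALSE
          c2 <- col; c2[b] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb columns that became subsets of another
      drop <- rep(FALSE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || drop[cj]) next
          if (all(!cols[[ci]] | cols[[cj]]) &&
              !identical(cols[[ci]], cols[[cj]])) {
            drop[ci] <- TRUE
            break
          }
        }
      }
      # identical duplicates: keep the first
      keys <- vapply(cols, function(c) paste(c, collapse = ""), character(1))
      drop <- drop | duplicated(keys)
      cols <- cols[!drop]
    }
  }
  # order columns by their highest-mean member, then letter them a, b, c...
  first_member <- vapply(cols, function(col) min(match(which(col), ord)),
                         numeric(1))
  cols <- cols[order(first_member)]
  lab <- make_letter_labels(length(cols))
  out <- vapply(seq_len(k), function(g) {
    paste(lab[vapply(cols, `[`, TRUE, g)], collapse = "")
  }, character(1))
  stats::setNames(out, rownames(sig))
}

make_letter_labels <- function(n) {
  if (n <= 26) letters[seq_len(n)]
  else c(letters, paste0(rep(letters, each = 26), letters))[seq_len(n)]
}

#' PCA summary of a community matrix
#'
#' Centered (optionally unit-variance scaled) principal component analysis
#' via singular value decomposition, as used to ordinate CLPP profiles and
#' niche-segment matrices. Constant columns are dropped with a warning.
#' Axis signs follow a deterministic convention: each axis is flipped so
#' that its largest-magnitude loading is positive.
#'
#' @param m Numeric matrix, samples x variables (>= 2 samples).
#' @param scale `"none"` (default; OD units are commensurable) or
#'   `"unit-variance"`.
#' @return List of class `pca_summary` with `variance` (percent per axis,
#'   non-increasing), `scores` (samples x axes) and `loadings`
#'   (variables x axes).
#' @export
pca_summary <- function(m, scale = c("none", "unit-variance")) {
  scale <- match.arg(scale)
  if (is.null(dim(m)) || nrow(m) < 2) stop("PCA needs at least 2 samples")
  if (ncol(m) < 2) stop("PCA needs at least 2 variables")
  const <- apply(m, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 non-constant variables")
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = scale == "unit-variance")
  flip <- vapply(seq_len(ncol(fit$rotation)), function(a) {
    l <- fit$rotation[, a]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  variance <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  names(variance) <- colnames(fit$x)
  structure(list(variance = variance, scores = scores, loadings = loadings),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("PCA summary:", length(x$variance), "axes\n")
  v <- round(x$variance[seq_len(min(4, length(x$variance)))], 2)
  cat("  variance explained (%):", paste(v, collapse = ", "), "...\n")
  invisible(x)
}
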