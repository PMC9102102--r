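# Shared fixtures and independent oracles.

catalog <- ecoplate_catalog()
codes31 <- substrate_codes(catalog)

# Random non-negative profile over the 31 substrates.
rand_profile <- function(scale = 2) {
  stats::setNames(stats::runif(31, 0, scale), codes31)
}

# A niche range built directly from given per-substrate triples.
range_from <- function(lower, center, upper, codes = names(center)) {
  structure(data.frame(code = codes, lower = lower, center = center,
                       upper = upper, row.names = NULL),
            class = c("niche_range", "data.frame"))
}

# Independent decomposition oracle: measures the deviation interval between
# the control mean and the observed response on a fine grid, splitting the
# above-mean part at the control maximum and the below-mean part at the
# control minimum.
oracle_decompose_one <- function(x, lower, center, upper, n = 200001) {
  if (x >= center) {
    u <- seq(center, x, length.out = n)
    du <- if (x > center) (x - center) / (n - 1) else 0
    c(intensification = sum(u[-1] <= upper) * du,
      expansion = sum(u[-1] > upper) * du,
      narrowing = 0, contraction = 0)
  } else {
    u <- seq(x, center, length.out = n)
    du <- (center - x) / (n - 1)
    c(intensification = 0, expansion = 0,
      narrowing = sum(u[-1] >= lower) * du,
      contraction = sum(u[-1] < lower) * du)
  }
}

# Pairwise LSD significance computed from first principles (no package
# code): pooled within-group mean square, two-sided t test at alpha.
oracle_pairwise_sig <- function(values, alpha = 0.05) {
  k <- length(values)
  n <- lengths(values)
  m <- vapply(values, mean, numeric(1))
  mse <- sum(unlist(lapply(values, function(v) (v - mean(v))^2))) /
    (sum(n) - k)
  dfw <- sum(n) - k
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tstat <- abs(m[i] - m[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
      sig[i, j] <- sig[j, i] <- 2 * stats::pt(tstat, dfw, lower.tail = FALSE) < alpha
    }
  }
  sig
}

# Write a minimal grid-dialect plate file; od8x12 is a list of 8x12
# matrices, one per block, with matching meta rows.
write_grid_file <- function(path, meta, blocks) {
  lines <- character()
  for (b in seq_along(blocks)) {
    lines <- c(lines, "plate,sample,time",
               paste(meta[[b]], collapse = ","),
               vapply(1:8, function(r) {
                 paste(c(LETTERS[r], format(blocks[[b]][r, ], trim = TRUE)),
                       collapse = ",")
               }, character(1)))
  }
  writeLines(lines, path)
  path
}

# A full 96-well OD vector where every substrate well of catalog entry i
# has `value[i]` and the three water wells have `water`.
grid_od <- function(values32, water = NA) {
  od <- numeric(96)
  names(od) <- as.vector(vapply(1:12, function(j) paste0(LETTERS[1:8], j),
                                character(8)))
  for (i in 1:32) {
    for (b in 1:3) {
      col <- (b - 1) * 4 + (i - 1) %/% 8 + 1
      row <- (i - 1) %% 8 + 1
      od[paste0(LETTERS[row], col)] <- values32[i]
    }
  }
  od
}

water_index <- which(catalog$guild == "W")
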