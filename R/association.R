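#' Sum segment components over functional guilds
#'
#' @param decomp A [niche_decompose()] result.
#' @param cat Substrate catalog.
#' @return List with one samples x guilds matrix per segment; guild columns
#'   in alphabetical order (AA, AM, CH, CX, P).
#' @export
guild_sums <- function(decomp, cat = ecoplate_catalog()) {
  first <- decomp[[1]]
  guilds <- guild_of(colnames(first), cat)
  lapply(decomp[segment_names()], function(m) {
    gs <- t(rowsum(t(m), group = factor(guilds, levels = guild_labels())))
    gs[, guild_labels(), drop = FALSE]
  })
}

#' Treatment-level guild x segment matrix
#'
#' Per sample, each segment is summed over every guild's substrates; the
#' guild values are then averaged per treatment (mean and standard error
#' over replicates) and LSD letters are attached per guild x segment.
#'
#' @param decomp A [niche_decompose()] over all samples.
#' @param design Design data frame covering the decomposed samples.
#' @param cat Substrate catalog.
#' @param alpha Significance level for the letter display.
#' @param treatments Optional subset/order of treatments to report
#'   (defaults to all treatments in `design`).
#' @return Long data frame: `treatment`, `guild`, `segment`, `mean`, `se`,
#'   `letter`, plus per guild x segment ANOVA `F` and `p` in attribute
#'   `anova`.
#' @export
guild_segment_table <- function(decomp, design, cat = ecoplate_catalog(),
                                alpha = 0.05, treatments = NULL) {
  design <- validate_design(design)
  gs <- guild_sums(decomp, cat)
  trt <- design$treatment[match(rownames(decomp[[1]]), design$sample_id)]
  if (anyNA(trt)) stop("decomposed sample(s) missing from the design table")
  if (is.null(treatments)) treatments <- unique(trt)
  rows <- list()
  anova_rows <- list()
  for (seg in segment_names()) {
    for (g in guild_labels()) {
      vals <- split(gs[[seg]][, g], trt)[treatments]
      mu <- vapply(vals, mean, numeric(1))
      se <- vapply(vals, function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
      letters <- if (all(lengths(vals) >= 2) && length(vals) >= 2) {
        lsd_letters(vals, alpha = alpha)
      } else rep(NA_character_, length(vals))
      rows[[paste(seg, g)]] <- data.frame(
        treatment = treatments, guild = g, segment = seg,
        mean = unname(mu), se = unname(se),
        letter = unname(letters[treatments]), row.names = NULL)
      if (all(lengths(vals) >= 2) && length(vals) >= 2) {
        a <- one_way_anova(vals)
        anova_rows[[paste(seg, g)]] <- data.frame(
          segment = seg, guild = g, F = a$F, p = a$p, row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "anova") <- do.call(rbind, c(anova_rows, list(make.row.names = FALSE)))
  out
}

# Shared ranking core for guild and functional-group associations.
# Order: value (descending, full precision), then all-segment total
# (descending), then label (alphabetical). A tie is flagged whenever the
# reporting precision cannot distinguish the chosen pair internally or from
# the runner-up.
rank_top_pair <- function(values, totals = NULL, digits = 2) {
  stopifnot(!is.null(names(values)))
  tot <- if (is.null(totals)) stats::setNames(rep(0, length(values)),
                                              names(values))
         else totals[names(values)]
  ord <- order(-values, -tot, names(values))
  v <- values[ord]
  r <- round(v, digits)
  tie <- length(v) >= 2 && (r[1] == r[2] || (length(v) >= 3 && r[2] == r[3]))
  list(first = names(v)[1],
       second = if (length(v) >= 2) names(v)[2] else "",
       tie = tie)
}

format_pair <- function(first, second) {
  if (!nzchar(second)) return(first)
  paste0(first, "\u2013", second)
}

#' Guild association of one treatment x segment
#'
#' Ranks the five guild-level segment values and names the top two as the
#' treatment's guild association for that niche segment, e.g. `"CH–CX"`.
#' Ties at full precision are broken by the guild's total over all four
#' segments, then alphabetically; a pair whose members cannot be
#' distinguished at the reporting precision is flagged.
#'
#' @param values Named numeric of the 5 guild segment values.
#' @param totals Optional named numeric of each guild's all-segment total
#'   (the tie-breaker).
#' @param digits Reporting precision used for tie flagging (default 2).
#' @return List with `first`, `second`, `pair` (en-dash joined) and `tie`.
#' @examples
#' guild_association(c(AA = 0.77, AM = 0.10, CH = 2.83, CX = 1.65, P = 2.11))
#' @export
guild_association <- function(values, totals = NULL, digits = 2) {
  if (length(values) != length(guild_labels()) ||
      !setequal(names(values), guild_labels())) {
    stop("expected one value per guild (", paste(guild_labels(), collapse = ", "), ")")
  }
  res <- rank_top_pair(values, totals, digits)
  res$pair <- format_pair(res$first, res$second)
  res
}

#' Dominant and codominant functional groups of one treatment x segment
#'
#' Ranks the 31 per-substrate treatment means of one segment and names the
#' top two substrate codes (the dominant-codominant functional groups),
#' e.g. `"CH9–CH1"`. Substrates with zero mean never enter the pair: an
#' all-zero segment yields an empty flagged pair, a single active substrate
#' a flagged pair without codominant.
#'
#' @param means Named numeric of per-substrate segment means.
#' @param totals Optional named numeric tie-breaker (all-segment substrate
#'   totals).
#' @param digits Reporting precision used for tie flagging.
#' @return List with `first`, `second`, `pair` and `tie`.
#' @export
dominance_codominance <- function(means, totals = NULL, digits = 2) {
  stopifnot(!is.null(names(means)))
  active <- means[means > 0]
  if (!length(active)) {
    return(list(first = "", second = "", pair = "", tie = TRUE))
  }
  if (length(active) == 1L) {
    return(list(first = names(active), second = "", pair = names(active),
                tie = TRUE))
  }
  res <- rank_top_pair(active, totals, digits)
  res$pair <- format_pair(res$first, res$second)
  res
}

#' Normalise an association pair string
#'
#' Accepts ASCII hyphens on input and returns the canonical en-dash form.
#'
#' @param x Character vector of pair strings (e.g. `"CH-CX"`).
#' @return The same pairs joined with an en dash.
#' @export
association_pair <- function(x) {
  gsub("-", "\u2013", x, fixed = TRUE)
}
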