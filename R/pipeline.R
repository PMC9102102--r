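#' Full DEMSA analysis of a profile matrix
#'
#' Runs the whole model in memory: control niche range, four-segment
#' decomposition of every sample, conventional CLPP summary, guild x
#' segment matrix, synthetic segment indices, functional alteration, guild
#' and functional-group associations, shared-with-control profiles,
#' within- and between-community resemblance, and PCA summaries of the raw,
#' shared and segment matrices.
#'
#' Treatment-level DEMSA blocks (guild matrix, indices, alteration,
#' associations, resemblance) are reported for the non-control treatments;
#' the control's own decomposition against its own range (used by
#' diagnostics) contains no expansion or contraction by construction.
#'
#' @param profiles Profile matrix, samples x 31 substrates.
#' @param design Design data frame covering the samples.
#' @param control Control treatment label.
#' @param alpha Significance level for letter displays.
#' @param include_control_between Passed to [between_resemblance()].
#' @param pca_scale Passed to [pca_summary()].
#' @param cat Substrate catalog.
#' @return A list of class `demsa_report`; see the vignette for a guided
#'   tour of its components.
#' @export
demsa_report <- function(profiles, design, control, alpha = 0.05,
                         include_control_between = TRUE,
                         pca_scale = "none", cat = ecoplate_catalog()) {
  design <- validate_design(design, control = control)
  missing_ids <- setdiff(design$sample_id, rownames(profiles))
  if (length(missing_ids)) {
    stop("design sample(s) missing from profiles: ",
         paste(missing_ids, collapse = ", "))
  }
  profiles <- profiles[design$sample_id, , drop = FALSE]
  is_ctrl <- design$treatment == control
  treatments <- setdiff(unique(design$treatment), control)

  range <- niche_range(profiles[is_ctrl, , drop = FALSE])
  control_total <- sum(range$center)
  decomp_all <- niche_decompose(profiles, range)
  treated <- design$sample_id[!is_ctrl]
  decomp <- lapply(decomp_all, function(m) m[treated, , drop = FALSE])
  class(decomp) <- "niche_decomposition"
  design_trt <- design[!is_ctrl, , drop = FALSE]

  table1 <- clpp_summary(profiles, design, alpha = alpha)
  guild_table <- guild_segment_table(decomp, design_trt, cat, alpha = alpha,
                                     treatments = treatments)

  idx <- segment_indices(decomp, profiles[treated, , drop = FALSE])
  idx$treatment <- design_trt$treatment[match(idx$sample_id,
                                              design_trt$sample_id)]
  index_table <- summarize_metrics(idx, segment_names(), alpha)

  fa <- data.frame(
    sample_id = treated,
    treatment = design_trt$treatment,
    alteration = functional_alteration(rowSums(profiles[treated, , drop = FALSE]),
                                       control_total))
  alteration_table <- summarize_metrics(fa, "alteration", alpha)

  associations <- association_tables(decomp, design_trt, treatments, cat)

  shared <- common_with_control(profiles, range)
  within <- do.call(rbind, lapply(treatments, function(t) {
    w <- within_resemblance(profiles[design$sample_id[design$treatment == t], ,
                                     drop = FALSE])
    data.frame(treatment = t, mean = w$mean, se = w$se)
  }))
  within_letters <- lsd_letters(
    lapply(stats::setNames(treatments, treatments), function(t) {
      within_resemblance(profiles[design$sample_id[design$treatment == t], ,
                                  drop = FALSE])$values
    }), alpha = alpha)
  within$letter <- unname(within_letters[within$treatment])
  between_all <- between_resemblance(profiles, design,
                                     include_control = include_control_between,
                                     control = control)
  between <- between_all[between_all$treatment %in% treatments, , drop = FALSE]

  # segment matrices routinely carry all-zero substrate columns; the
  # constant-column drop is silent here and reported via the axis counts
  pca <- list(profiles = pca_summary(profiles, scale = pca_scale),
              shared = suppressWarnings(pca_summary(shared, scale = pca_scale)))
  for (seg in segment_names()) {
    pca[[seg]] <- try(suppressWarnings(
      pca_summary(decomp_all[[seg]], scale = pca_scale)), silent = TRUE)
    if (inherits(pca[[seg]], "try-error")) pca[[seg]] <- NULL
  }

  structure(list(
    control = control, treatments = treatments, design = design,
    range = range, control_total = control_total,
    decomposition = decomp_all,
    table1 = table1, guild_table = guild_table,
    index_table = index_table, indices = idx,
    alteration_table = alteration_table, alteration = fa,
    associations = associations,
    shared = shared, within = within, between = between,
    pca = pca), class = "demsa_report")
}

# Guild and functional-group association blocks, one row per
# treatment x segment.
association_tables <- function(decomp, design_trt, treatments,
                               cat = ecoplate_catalog()) {
  gs <- guild_sums(decomp, cat)
  trt <- design_trt$treatment[match(rownames(decomp[[1]]),
                                    design_trt$sample_id)]
  rows <- list()
  for (t in treatments) {
    guild_means <- vapply(gs, function(m) {
      colMeans(m[trt == t, , drop = FALSE])
    }, numeric(length(guild_labels())))
    guild_totals <- rowSums(guild_means)
    sub_means <- vapply(decomp, function(m) {
      colMeans(m[trt == t, , drop = FALSE])
    }, numeric(ncol(decomp[[1]])))
    sub_totals <- rowSums(sub_means)
    for (seg in segment_names()) {
      ga <- guild_association(guild_means[, seg], totals = guild_totals)
      dc <- dominance_codominance(sub_means[, seg], totals = sub_totals)
      rows[[paste(t, seg)]] <- data.frame(
        treatment = t, segment = seg,
        guild_pair = ga$pair, guild_tie = ga$tie,
        group_pair = dc$pair, group_tie = dc$tie,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.demsa_report <- function(x, ...) {
  cat("DEMSA report:", nrow(x$design), "samples,",
      length(x$treatments), "treatments vs control", x$control, "\n")
  cat("  control mean total activity:", round(x$control_total, 2), "OD\n")
  cat("  components: table1, guild_table, index_table, alteration_table,\n",
      "    associations, within, between, shared, pca, decomposition\n")
  invisible(x)
}

#' Run the DEMSA pipeline on files and write a report bundle
#'
#' Reads plate data and a design table, blank-corrects, selects the plateau
#' timepoint per sample, runs [demsa_report()] and writes the output bundle:
#' `table1.csv`, `table2_guilds.csv`, `table2_indices.csv`,
#' `table2_associations.csv`, `table2_community.csv`, `pca_variance.csv`,
#' `pca_scores_*.csv`, `report.json` and `run.log`. On failure, partially
#' written outputs are removed.
#'
#' @param input Path to the plate CSV (see [read_ecoplate()]).
#' @param design Path to the design CSV, or a design data frame.
#' @param out_dir Output directory (created if needed).
#' @param layout `"grid"` or `"long"`.
#' @param control Control treatment label.
#' @param plateau Plateau policy for [select_plateau()].
#' @param alpha Significance level.
#' @param pca_scale `"none"` or `"unit-variance"`.
#' @param include_control_between Passed to [between_resemblance()].
#' @param cat Substrate catalog.
#' @return The `demsa_report`, invisibly.
#' @export
demsa_run <- function(input, design, out_dir, layout = "long",
                      control = "V1", plateau = "last", alpha = 0.05,
                      pca_scale = "none", include_control_between = TRUE,
                      cat = ecoplate_catalog()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ..., "\n",
        file = log_path, append = TRUE)
  }
  emit <- function(obj, name, ...) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE, ...)
    written <<- c(written, path)
    logf("wrote", name)
    path
  }
  res <- tryCatch({
    logf("run start: input =", input, "layout =", layout,
         "control =", control, "plateau =", plateau)
    if (is.character(design)) design <- read_design(design, control = control)
    design <- validate_design(design, control = control)
    if (grepl("\\.csv$", input) &&
        all(c("sample_id", "substrate_code", "response") %in%
              names(utils::read.csv(input, nrows = 1)))) {
      profiles <- read_profiles(input)   # already blank-corrected profiles
    } else {
      readings <- read_ecoplate(input, layout = layout)
      ids <- vapply(readings, `[[`, "", "sample_id")
      profs <- lapply(split(readings, ids), function(series) {
        blank_correct(select_plateau(series, policy = plateau, cat = cat), cat)
      })
      profiles <- profile_matrix(profs)
    }
    report <- demsa_report(profiles, design, control = control, alpha = alpha,
                           include_control_between = include_control_between,
                           pca_scale = pca_scale, cat = cat)
    emit(report$table1, "table1.csv")
    emit(report$guild_table, "table2_guilds.csv")
    emit(report$index_table, "table2_indices.csv")
    emit(report$associations, "table2_associations.csv", fileEncoding = "UTF-8")
    community <- merge(report$alteration_table,
                       merge(stats::setNames(report$within,
                                             c("treatment", "within_mean",
                                               "within_se", "within_letter")),
                             stats::setNames(report$between,
                                             c("treatment", "between_mean",
                                               "between_se")),
                             by = "treatment"),
                       by = "treatment")
    emit(community, "table2_community.csv")
    pca_var <- do.call(rbind, lapply(names(report$pca), function(nm) {
      v <- report$pca[[nm]]$variance
      data.frame(matrix_name = nm, axis = seq_along(v), variance_pct = unname(v))
    }))
    emit(pca_var, "pca_variance.csv")
    for (nm in names(report$pca)) {
      sc <- report$pca[[nm]]$scores
      emit(data.frame(sample_id = rownames(sc), sc[, seq_len(min(4, ncol(sc))),
                                                   drop = FALSE]),
           paste0("pca_scores_", nm, ".csv"))
    }
    json_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_json(report), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, json_path)
    logf("run complete")
    report
  }, error = function(e) {
    logf("run FAILED:", conditionMessage(e))
    file.remove(written[file.exists(written)])
    stop(e)
  })
  invisible(res)
}

# Plain-list view of a report for JSON serialisation.
report_to_json <- function(report) {
  list(
    control = report$control,
    treatments = report$treatments,
    control_total = report$control_total,
    range = report$range[, c("code", "lower", "center", "upper")],
    table1 = report$table1,
    guild_table = report$guild_table,
    index_table = report$index_table,
    indices = report$indices,
    alteration = report$alteration,
    alteration_table = report$alteration_table,
    associations = report$associations,
    within = report$within,
    between = report$between,
    pca_variance = lapply(report$pca, function(p) unname(p$variance))
  )
}
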