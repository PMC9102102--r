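#' @keywords internal
well_names <- function() {
  as.vector(vapply(1:12, function(j) paste0(LETTERS[1:8], j), character(8)))
}

# Well holding catalog entry i (1..32, block-column-major) in block b (1..3).
block_well <- function(i, b) {
  col_within <- (i - 1L) %/% 8L + 1L
  row <- (i - 1L) %% 8L + 1L
  paste0(LETTERS[row], (b - 1L) * 4L + col_within)
}

new_plate_reading <- function(plate_id, sample_id, time_h, od) {
  structure(list(plate_id = plate_id, sample_id = sample_id,
                 time_h = as.numeric(time_h), od = od),
            class = "plate_reading")
}

#' @export
print.plate_reading <- function(x, ...) {
  cat("EcoPlate reading: plate", x$plate_id, "sample", x$sample_id,
      "at", x$time_h, "h;", length(x$od), "values\n")
  invisible(x)
}

#' Read EcoPlate optical-density data
#'
#' Reads raw 590 nm optical densities from CSV in one of two dialects.
#'
#' **Grid layout**: one 8 x 12 block per plate x timepoint. Each block is a
#' header line `plate,sample,time`, a values line (e.g. `PL1,S1,24`), an
#' optional column-number line, then eight rows of twelve comma-separated OD
#' values, optionally prefixed by the row letter A..H.
#'
#' **Long layout**: columns `sample_id`, `well` *or* `substrate_code`,
#' `time_h`, `od` (an optional `plate_id` column is kept). Well-level rows
#' must cover all 96 wells per sample x timepoint; code-level rows must
#' cover the 31 substrate codes plus `W` and are treated as one
#' already-averaged block.
#'
#' @param path CSV file path.
#' @param layout `"grid"` or `"long"`.
#' @return A list of plate readings, each with fields `plate_id`,
#'   `sample_id`, `time_h` and a named `od` vector (96 wells, or 32
#'   substrate codes for code-level long input).
#' @export
read_ecoplate <- function(path, layout = c("grid", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  readings <- switch(layout,
                     grid = read_ecoplate_grid(path),
                     long = read_ecoplate_long(path))
  check_timepoints(readings, path)
  readings
}

read_ecoplate_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^\\s*plate\\s*,", lines, ignore.case = TRUE)
  if (!length(starts)) {
    stop("no grid blocks found in ", path,
         " (expected header lines 'plate,sample,time')")
  }
  readings <- list()
  for (s in starts) {
    if (s + 1L > length(lines)) stop(path, " line ", s, ": truncated block")
    meta <- strsplit(lines[s + 1L], ",")[[1]]
    if (length(meta) < 3L) {
      stop(path, " line ", s + 1L, ": expected 'plate_id,sample_id,time'")
    }
    i <- s + 2L
    # optional column-number ruler line ("" or "row" first field)
    first <- trimws(strsplit(lines[i], ",")[[1]][1])
    if (first == "" || tolower(first) == "row" || first == "1") i <- i + 1L
    od <- matrix(NA_real_, 8, 12)
    for (r in 1:8) {
      ln <- i + r - 1L
      if (ln > length(lines)) {
        stop(path, " line ", ln, ": block ends early, row ",
             LETTERS[r], " missing")
      }
      fields <- trimws(strsplit(lines[ln], ",")[[1]])
      if (length(fields) == 13L) fields <- fields[-1]
      if (length(fields) != 12L) {
        stop(path, " line ", ln, ": expected 12 OD values, found ",
             length(fields))
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (anyNA(vals)) {
        stop(path, " line ", ln, ": non-numeric OD value '",
             fields[which(is.na(vals))[1]], "'")
      }
      od[r, ] <- vals
    }
    odv <- as.vector(od)            # column-major = A1..H1, A2..H2, ...
    names(odv) <- well_names()
    readings[[length(readings) + 1L]] <-
      new_plate_reading(trimws(meta[1]), trimws(meta[2]), trimws(meta[3]), odv)
  }
  readings
}

read_ecoplate_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key_col <- if ("well" %in% names(df)) "well" else
    if ("substrate_code" %in% names(df)) "substrate_code" else
      stop(path, ": long layout needs a 'well' or 'substrate_code' column")
  need <- c("sample_id", key_col, "time_h", "od")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!is.numeric(df$od)) stop(path, ": non-numeric values in 'od'")
  if (!"plate_id" %in% names(df)) df$plate_id <- df$sample_id
  full <- if (key_col == "well") well_names() else NULL
  out <- list()
  for (grp in split(df, list(df$plate_id, df$sample_id, df$time_h), drop = TRUE)) {
    od <- grp$od
    names(od) <- grp[[key_col]]
    if (key_col == "well") {
      found <- intersect(full, names(od))
      if (length(found) != 96L || length(od) != 96L) {
        stop(path, ": 96 wells expected, ", length(found), " found for sample ",
             grp$sample_id[1], " at ", grp$time_h[1], " h")
      }
      od <- od[full]
    }
    out[[length(out) + 1L]] <- new_plate_reading(grp$plate_id[1],
                                                 grp$sample_id[1],
                                                 grp$time_h[1], od)
  }
  out[order(vapply(out, `[[`, "", "sample_id"),
            vapply(out, `[[`, 0, "time_h"))]
}

check_timepoints <- function(readings, path) {
  ids <- vapply(readings, `[[`, "", "plate_id")
  for (p in unique(ids)) {
    tp <- vapply(readings[ids == p], `[[`, 0, "time_h")
    if (anyNA(tp) || any(tp < 0)) {
      stop(path, ": invalid timepoint for plate ", p)
    }
    if (anyDuplicated(tp)) {
      stop(path, ": duplicated timepoint(s) for plate ", p, ": ",
           paste(tp[duplicated(tp)], collapse = ", "))
    }
  }
  invisible(readings)
}

#' Blank-correct a plate reading into a substrate profile
#'
#' Converts raw well ODs into one response per substrate. For a 96-well
#' reading, each of the three 32-well blocks contributes its own water
#' blank: every substrate well is corrected by subtracting the water OD of
#' its block, negative corrected values are clipped to 0, and the three
#' block values are averaged. Code-level readings (already one value per
#' substrate) are corrected against their single `W` entry.
#'
#' @param reading A plate reading from [read_ecoplate()].
#' @param cat A substrate catalog.
#' @return A `sample_profile`: list with `sample_id`, `time_h`, `x` (named
#'   vector of 31 non-negative responses, in catalog order) and `total`
#'   (their sum).
#' @export
blank_correct <- function(reading, cat = ecoplate_catalog()) {
  od <- reading$od
  codes <- substrate_codes(cat)
  idx <- which(cat$guild != "W")
  w_idx <- which(cat$guild == "W")
  if (all(well_names() %in% names(od))) {
    x <- vapply(seq_along(idx), function(k) {
      per_block <- vapply(1:3, function(b) {
        v <- od[block_well(idx[k], b)] - od[block_well(w_idx, b)]
        max(0, v)
      }, numeric(1))
      mean(per_block)
    }, numeric(1))
  } else if (all(c(codes, cat$code[w_idx]) %in% names(od))) {
    x <- pmax(0, od[codes] - od[cat$code[w_idx]])
  } else {
    stop("reading has neither 96 named wells nor the 32 substrate codes")
  }
  x <- unname(x)
  names(x) <- codes
  structure(list(sample_id = reading$sample_id, time_h = reading$time_h,
                 x = x, total = sum(x)),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("Sample profile", x$sample_id, "at", x$time_h,
      "h: total activity", round(x$total, 3), "\n")
  invisible(x)
}

#' Select the plateau-phase reading of a plate series
#'
#' EcoPlates are incubated until colour development plateaus; one timepoint
#' per sample enters the analysis.
#'
#' @param readings List of plate readings for one sample (any order).
#' @param policy `"last"` (default, the latest timepoint), `"max_awcd"` (the
#'   timepoint maximising average well colour development after blank
#'   correction), or `"fixed:T"` (the timepoint nearest to `T` hours; ties
#'   break toward the later reading, and a warning is issued when the
#'   nearest reading is more than 12 h away).
#' @param cat Substrate catalog, used by `max_awcd`.
#' @return One plate reading.
#' @export
select_plateau <- function(readings, policy = "last", cat = ecoplate_catalog()) {
  if (!length(readings)) stop("empty plate series")
  tp <- vapply(readings, `[[`, 0, "time_h")
  if (identical(policy, "last")) {
    return(readings[[which.max(tp)]])
  }
  if (identical(policy, "max_awcd")) {
    awcds <- vapply(readings, function(r) mean(blank_correct(r, cat)$x),
                    numeric(1))
    return(readings[[which.max(awcds)]])
  }
  if (grepl("^fixed:", policy)) {
    t0 <- as.numeric(sub("^fixed:", "", policy))
    if (is.na(t0)) stop("bad plateau policy: ", policy)
    d <- abs(tp - t0)
    best <- which(d == min(d))
    pick <- best[which.max(tp[best])]   # tie toward the later reading
    if (d[pick] > 12) {
      warning("nearest timepoint to ", t0, " h is ", tp[pick], " h (|dt| = ",
              d[pick], " h > 12 h)")
    }
    return(readings[[pick]])
  }
  stop("unknown plateau policy: ", policy)
}

#' Assemble sample profiles into a community matrix
#'
#' @param profiles List of `sample_profile` objects.
#' @return Numeric matrix, samples x 31 substrates; rownames are sample ids,
#'   colnames substrate codes in catalog order.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  m <- do.call(rbind, lapply(profiles, `[[`, "x"))
  rownames(m) <- vapply(profiles, `[[`, "", "sample_id")
  m
}

#' Read and write canonical long-format profiles
#'
#' The canonical on-disk form is a long CSV with columns `sample_id`,
#' `substrate_code`, `response`.
#'
#' @param x Profile matrix (samples x substrates).
#' @param path CSV file path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns a profile matrix.
#' @export
write_profiles <- function(x, path) {
  df <- data.frame(sample_id = rep(rownames(x), each = ncol(x)),
                   substrate_code = rep(colnames(x), times = nrow(x)),
                   response = as.vector(t(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "substrate_code", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  ids <- unique(df$sample_id)
  codes <- unique(df$substrate_code)
  m <- matrix(NA_real_, length(ids), length(codes),
              dimnames = list(ids, codes))
  m[cbind(match(df$sample_id, ids), match(df$substrate_code, codes))] <-
    df$response
  if (anyNA(m)) stop(path, ": incomplete sample x substrate grid")
  m
}

#' Read a design table
#'
#' @param path CSV with columns `sample_id`, `treatment`, `replicate`.
#' @param control Label of the control treatment (checked for presence and
#'   at least two replicates).
#' @return Validated design data frame.
#' @export
read_design <- function(path, control = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design(df, control)
}

#' @rdname read_design
#' @param design A design data frame.
#' @export
validate_design <- function(design, control = NULL) {
  need <- c("sample_id", "treatment", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) {
    stop("design: duplicated sample_id(s): ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  }
  if (any(design$replicate < 1 | design$replicate != round(design$replicate))) {
    stop("design: replicate must be a positive integer")
  }
  if (!is.null(control)) {
    n_ctrl <- sum(design$treatment == control)
    if (n_ctrl == 0) stop("control treatment '", control, "' not found")
    if (n_ctrl < 2) stop("control treatment '", control,
                         "' needs at least 2 replicates, found ", n_ctrl)
  }
  design
}
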