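#' The Biolog EcoPlate substrate catalog
#'
#' An EcoPlate carries 31 carbon substrates plus a water blank, replicated in
#' three 32-well blocks. Each substrate (a *functional group*) belongs to one
#' of five chemical classes (*functional guilds*): carbohydrates (`CH`, 10
#' substrates), carboxylic and acetic acids (`CX`, 9), amino acids (`AA`, 6),
#' polymers (`P`, 4) and amines/amides (`AM`, 2). The water blank carries the
#' pseudo-guild `W`.
#'
#' Catalog rows are ordered as the wells are laid out within one 32-well
#' block (column-major: wells A1..H1, A2..H2, A3..H3, A4..H4), so row `i`
#' of the catalog is the substrate in block position `i`.
#'
#' @param path Path to a catalog CSV with columns `substrate`, `code`,
#'   `guild`. Defaults to the catalog shipped with the package.
#' @return A data frame with columns `substrate`, `code`, `guild` (32 rows:
#'   31 coded substrates plus water), validated against the EcoPlate layout.
#' @examples
#' cat <- ecoplate_catalog()
#' table(cat$guild)
#' @export
ecoplate_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ecoplate_catalog.csv", package = "demsa",
                        mustWork = TRUE)
  }
  cat <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_catalog(cat)
}

#' Validate a substrate catalog
#'
#' Checks the structural invariants of the EcoPlate catalog: 32 entries (31
#' coded substrates plus one water blank), unique codes, known guild labels
#' and the fixed guild sizes CH=10, CX=9, AA=6, P=4, AM=2.
#'
#' @param cat A data frame with columns `substrate`, `code`, `guild`.
#' @return The validated catalog, invisibly unchanged.
#' @export
validate_catalog <- function(cat) {
  need <- c("substrate", "code", "guild")
  if (!all(need %in% names(cat))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  dup <- cat$code[duplicated(cat$code)]
  if (length(dup)) {
    stop("duplicate substrate code(s) in catalog: ",
         paste(unique(dup), collapse = ", "))
  }
  known <- c(guild_labels(), "W")
  bad <- setdiff(unique(cat$guild), known)
  if (length(bad)) {
    bad_rows <- which(cat$guild %in% bad)
    stop("unknown guild label(s) ", paste(bad, collapse = ", "),
         " at catalog row(s) ", paste(bad_rows, collapse = ", "))
  }
  if (nrow(cat) != 32L) {
    stop("catalog must have 32 entries (31 substrates + water), found ",
         nrow(cat))
  }
  if (sum(cat$guild == "W") != 1L) {
    stop("catalog must contain exactly one water blank (guild W)")
  }
  sizes <- table(factor(cat$guild[cat$guild != "W"], levels = guild_labels()))
  expected <- c(AA = 6L, AM = 2L, CH = 10L, CX = 9L, P = 4L)
  if (!all(sizes[names(expected)] == expected)) {
    stop("guild sizes must be CH=10, CX=9, AA=6, P=4, AM=2; found ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  cat
}

#' @rdname ecoplate_catalog
#' @export
read_catalog <- function(path) {
  ecoplate_catalog(path = path)
}

#' The five EcoPlate functional-guild labels
#'
#' @return Character vector `c("AA", "AM", "CH", "CX", "P")` (alphabetical).
#' @export
guild_labels <- function() c("AA", "AM", "CH", "CX", "P")

#' Substrate codes of a catalog, in plate order
#'
#' @param cat A substrate catalog (see [ecoplate_catalog()]).
#' @return The 31 non-water substrate codes, in well order.
#' @export
substrate_codes <- function(cat = ecoplate_catalog()) {
  cat$code[cat$guild != "W"]
}

#' Map substrate codes to guilds
#'
#' @param codes Character vector of substrate codes.
#' @param cat A substrate catalog.
#' @return Character vector of guild labels, same length as `codes`.
#' @export
guild_of <- function(codes, cat = ecoplate_catalog()) {
  g <- cat$guild[match(codes, cat$code)]
  if (anyNA(g)) {
    stop("substrate code(s) not in catalog: ",
         paste(codes[is.na(g)], collapse = ", "))
  }
  g
}
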