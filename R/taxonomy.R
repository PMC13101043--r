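habitat_classes <- c("FRESHWATER", "MARINE_COASTAL", "TERRESTRIAL")
freshwater_groups <- c("RUNNING", "STANDING", "PEATLAND", "FOREST",
                       "GRASS_HEATH_COASTAL")
nutrient_levels <- c("OLIGOTROPHIC", "MESOTROPHIC", "EUTROPHIC")

#' Read the Annex I habitat classification table
#'
#' The table assigns every Annex I code one of three habitat classes
#' (freshwater / marine and coastal / terrestrial) and, for freshwater
#' codes, one of five freshwater groups (running water, standing water,
#' peatland, forest, grassland-heathland-coastal) and a nutrient level
#' (oligo-, meso- or eutrophic). The classification is expert knowledge and
#' therefore lives in a versioned data file, not in code; the shipped file
#' is a reconstruction and each row records its provenance in
#' `source_note`.
#'
#' Validity is enforced at load: duplicate codes are a hard error, as is a
#' freshwater row missing its group or nutrient, or a non-freshwater row
#' carrying either.
#'
#' @param path CSV with columns `habitat_code`, `habitat_class`,
#'   `freshwater_group`, `nutrient`, `source_note`. Defaults to the shipped
#'   table.
#' @return A tibble of class `n2k_taxonomy`.
#' @export
#' @examples
#' tax <- read_taxonomy()
#' table(tax$habitat_class)
read_taxonomy <- function(path = n2k_extdata("annex1_taxonomy.csv")) {
  tax <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  required <- c("habitat_code", "habitat_class", "freshwater_group",
                "nutrient")
  missing <- setdiff(required, names(tax))
  if (length(missing) > 0) {
    stop("taxonomy table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tax$habitat_code <- normalize_habitat_code(tax$habitat_code)$code
  for (col in c("freshwater_group", "nutrient")) {
    tax[[col]][!is.na(tax[[col]]) & !nzchar(trimws(tax[[col]]))] <- NA_character_
  }
  dup <- unique(tax$habitat_code[duplicated(tax$habitat_code)])
  if (length(dup) > 0) {
    stop("duplicate habitat_code(s) in taxonomy: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_class <- !tax$habitat_class %in% habitat_classes
  if (any(bad_class)) {
    stop("unknown habitat_class value(s): ",
         paste(unique(tax$habitat_class[bad_class]), collapse = ", "),
         call. = FALSE)
  }
  fw <- tax$habitat_class == "FRESHWATER"
  if (any(fw & (is.na(tax$freshwater_group) | is.na(tax$nutrient)))) {
    stop("freshwater taxonomy rows must carry a group and a nutrient level",
         call. = FALSE)
  }
  if (any(!fw & (!is.na(tax$freshwater_group) | !is.na(tax$nutrient)))) {
    stop("non-freshwater rows must not carry a group or nutrient level",
         call. = FALSE)
  }
  if (any(fw & !tax$freshwater_group %in% freshwater_groups) ||
      any(fw & !tax$nutrient %in% nutrient_levels)) {
    stop("unknown freshwater group or nutrient label", call. = FALSE)
  }
  class(tax) <- c("n2k_taxonomy", class(tax))
  tax
}

#' Look up the classification of Annex I habitat codes
#'
#' @param codes Character vector of normalized codes (uppercase, no
#'   asterisk).
#' @param taxonomy A table from [read_taxonomy()].
#' @return A tibble with one row per input code: `habitat_code`,
#'   `habitat_class`, `freshwater_group`, `nutrient`, `classified`. Codes
#'   absent from the taxonomy come back with `classified = FALSE` and `NA`
#'   fields — never a silent default.
#' @export
classify_habitat <- function(codes, taxonomy = read_taxonomy()) {
  idx <- match(codes, taxonomy$habitat_code)
  tibble::tibble(
    habitat_code = codes,
    habitat_class = taxonomy$habitat_class[idx],
    freshwater_group = taxonomy$freshwater_group[idx],
    nutrient = taxonomy$nutrient[idx],
    classified = !is.na(idx))
}

#' Annotate a curated dataset with habitat classifications
#'
#' @param curated An `n2k_curated` object from [curate()].
#' @param taxonomy A table from [read_taxonomy()].
#' @param on_unclassified `"keep"` records unclassified entries with `NA`
#'   class (reported), `"error"` aborts if any code is unclassified.
#' @return An `n2k_classified` list: `sites`, `entries` (with
#'   `habitat_class`, `freshwater_group`, `nutrient` columns), `audit`,
#'   `unclassified` (tibble of code, n_entries).
#' @export
attach_classifications <- function(curated, taxonomy = read_taxonomy(),
                                   on_unclassified = c("keep", "error")) {
  on_unclassified <- match.arg(on_unclassified)
  stopifnot(inherits(curated, "n2k_curated"))
  cls <- classify_habitat(curated$entries$habitat_code, taxonomy)
  entries <- dplyr::bind_cols(
    curated$entries,
    cls[c("habitat_class", "freshwater_group", "nutrient")])
  unclassified <- cls |>
    dplyr::filter(!.data$classified) |>
    dplyr::count(.data$habitat_code, name = "n_entries")
  if (on_unclassified == "error" && nrow(unclassified) > 0) {
    stop("unclassified habitat code(s): ",
         paste(unclassified$habitat_code, collapse = ", "), call. = FALSE)
  }
  structure(list(sites = curated$sites, entries = entries,
                 audit = curated$audit, unclassified = unclassified),
            class = c("n2k_classified", "n2k_curated"))
}

#' @export
print.n2k_classified <- function(x, ...) {
  cat("<n2k_classified>", nrow(x$sites), "sites,", nrow(x$entries),
      "entries (", sum(x$entries$habitat_class == "FRESHWATER", na.rm = TRUE),
      "freshwater ),", nrow(x$unclassified), "unclassified codes\n")
  invisible(x)
}
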