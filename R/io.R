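#' Describe the layout of a Natura 2000 export table
#'
#' Official exports of the Natura 2000 database vary in column casing and
#' naming across releases, so the mapping from semantic fields to physical
#' column names is configuration, not code. The defaults follow the 2021
#' tabular export.
#'
#' @param table One of `"sites"`, `"habitats"`, `"bioregions"`.
#' @param columns Named character vector overriding the default
#'   field -> column-name mapping for the table.
#' @param type_map Named character vector mapping raw site-type codes to
#'   `BD_ONLY` / `HD_ONLY` / `BOTH` (sites table only). The 2021 export uses
#'   A (SPA, Birds Directive only), B (SCI/SAC, Habitats Directive only) and
#'   C (identical boundaries, both directives).
#' @param cover_unit Unit of the habitat cover column: `"ha"` (hectares) or
#'   `"percent"` (per cent of site area; converted to hectares downstream).
#' @return A list of class `n2k_schema`.
#' @export
#' @examples
#' n2k_schema("sites")
n2k_schema <- function(table = c("sites", "habitats", "bioregions"),
                       columns = NULL, type_map = NULL,
                       cover_unit = c("ha", "percent")) {
  table <- match.arg(table)
  cover_unit <- match.arg(cover_unit)
  defaults <- list(
    sites = c(site_code = "SITECODE", site_type = "SITETYPE",
              total_area_ha = "AREAHA", country = "COUNTRY_CODE"),
    habitats = c(site_code = "SITECODE", habitat_code = "HABITATCODE",
                 cover_ha = "COVER_HA"),
    bioregions = c(site_code = "SITECODE", region = "BIOGEFRAPHICREG",
                   percent_of_site = "PERCENTAGE"))
  cols <- defaults[[table]]
  if (!is.null(columns)) cols[names(columns)] <- columns
  if (is.null(type_map)) {
    type_map <- c(A = "BD_ONLY", B = "HD_ONLY", C = "BOTH",
                  BD_ONLY = "BD_ONLY", HD_ONLY = "HD_ONLY", BOTH = "BOTH")
  }
  structure(list(table = table, columns = cols, type_map = type_map,
                 cover_unit = cover_unit),
            class = "n2k_schema")
}

# read a CSV as character columns and check the schema's required columns
read_raw_table <- function(path, schema, optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  required <- schema$columns[setdiff(names(schema$columns), optional)]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    stop("table '", schema$table, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw
}

num_or_na <- function(x) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

new_load_report <- function(table, n_rows, ...) {
  structure(c(list(table = table, n_rows = n_rows), list(...)),
            class = "n2k_load_report")
}

#' @export
print.n2k_load_report <- function(x, ...) {
  cat("<n2k_load_report> table:", x$table, "rows:", x$n_rows, "\n")
  for (f in setdiff(names(x), c("table", "n_rows"))) {
    v <- x[[f]]
    if (is.data.frame(v)) {
      cat(" ", f, ":", nrow(v), "entries\n")
    } else {
      cat(" ", f, ":", paste(utils::head(v, 5), collapse = ", "),
          if (length(v) > 5) "..." else "", "\n")
    }
  }
  invisible(x)
}

#' Extract the load report attached to a loaded table
#'
#' @param x A tibble returned by [read_sites()], [read_habitats()] or
#'   [read_bioregions()].
#' @return The `n2k_load_report`.
#' @export
load_report <- function(x) attr(x, "report")

#' Read the NATURA2000SITES table
#'
#' One record per site with its designation type and total area in hectares.
#' Loading never filters: rows with missing areas or duplicated site codes
#' are preserved so the curation audit trail is complete; the report counts
#' them.
#'
#' @param path Path to the CSV export.
#' @param schema An [n2k_schema()] for the sites table.
#' @return A tibble with columns `site_code`, `site_type`, `total_area_ha`,
#'   `country`, carrying an `n2k_load_report` attribute (see
#'   [load_report()]). Unknown site-type codes become `NA` and are reported.
#' @export
read_sites <- function(path, schema = n2k_schema("sites")) {
  stopifnot(inherits(schema, "n2k_schema"), schema$table == "sites")
  raw <- read_raw_table(path, schema, optional = "country")
  cols <- schema$columns
  out <- tibble::tibble(
    site_code = trimws(raw[[cols[["site_code"]]]]),
    site_type = unname(schema$type_map[trimws(raw[[cols[["site_type"]]]])]),
    total_area_ha = num_or_na(raw[[cols[["total_area_ha"]]]]),
    country = if (cols[["country"]] %in% names(raw)) {
      trimws(raw[[cols[["country"]]]])
    } else NA_character_)
  dup <- unique(out$site_code[duplicated(out$site_code)])
  if (length(dup) > 0) {
    warning("duplicate site_code(s) kept for audit: ",
            paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  n_unknown_type <- sum(is.na(out$site_type))
  report <- new_load_report("sites", nrow(out),
                            n_missing_area = sum(is.na(out$total_area_ha)),
                            duplicate_codes = dup,
                            n_unknown_type = n_unknown_type)
  attr(out, "report") <- report
  out
}

# normalize an Annex I habitat code: uppercase, trailing priority "*" stripped
normalize_habitat_code <- function(code) {
  code <- toupper(trimws(code))
  priority <- endsWith(code, "*")
  list(code = sub("\\*$", "", code), priority = priority)
}

#' Read the HABITATS table
#'
#' One record per (site, Annex I habitat) pair with the habitat's cover.
#' Codes are normalized to the 4-character uppercase form; a trailing `*`
#' (priority habitat) is stripped into a separate logical flag, since the
#' asterisk is metadata, not part of the code key.
#'
#' @inheritParams read_sites
#' @return A tibble with columns `site_code`, `habitat_code`, `priority`,
#'   `cover_ha` (missing covers preserved as `NA`), with a load-report
#'   attribute. If the schema declares `cover_unit = "percent"` the column is
#'   named `cover_percent` instead and conversion to hectares happens when
#'   joining against site areas.
#' @export
read_habitats <- function(path, schema = n2k_schema("habitats")) {
  stopifnot(inherits(schema, "n2k_schema"), schema$table == "habitats")
  raw <- read_raw_table(path, schema)
  cols <- schema$columns
  norm <- normalize_habitat_code(raw[[cols[["habitat_code"]]]])
  cover <- num_or_na(raw[[cols[["cover_ha"]]]])
  out <- tibble::tibble(
    site_code = trimws(raw[[cols[["site_code"]]]]),
    habitat_code = norm$code,
    priority = norm$priority,
    cover_ha = cover)
  if (schema$cover_unit == "percent") {
    names(out)[names(out) == "cover_ha"] <- "cover_percent"
  }
  bad_code <- !grepl("^[0-9][0-9A-Z]{3}$", out$habitat_code)
  report <- new_load_report("habitats", nrow(out),
                            n_missing_cover = sum(is.na(cover)),
                            n_priority = sum(norm$priority),
                            malformed_codes = unique(out$habitat_code[bad_code]))
  attr(out, "report") <- report
  out
}

#' Read the BIOREGION table
#'
#' One record per (site, biogeographic region) pair with the percentage of
#' the site's area falling in that region. Region spellings are mapped onto
#' the canonical 14-region vocabulary through an alias table; unknown
#' spellings are kept with region `"UNKNOWN"` and collected in the report.
#'
#' @inheritParams read_sites
#' @param aliases Alias table (`alias`, `region`) as from
#'   [n2k_region_aliases()].
#' @return A tibble with columns `site_code`, `region`, `percent_of_site`,
#'   with a load-report attribute.
#' @export
read_bioregions <- function(path, schema = n2k_schema("bioregions"),
                            aliases = n2k_region_aliases()) {
  stopifnot(inherits(schema, "n2k_schema"), schema$table == "bioregions")
  raw <- read_raw_table(path, schema)
  cols <- schema$columns
  raw_region <- trimws(raw[[cols[["region"]]]])
  lookup <- stats::setNames(aliases$region, aliases$alias)
  region <- unname(lookup[raw_region])
  unknown <- is.na(region) & !is.na(raw_region) & nzchar(raw_region)
  region[unknown] <- "UNKNOWN"
  out <- tibble::tibble(
    site_code = trimws(raw[[cols[["site_code"]]]]),
    region = region,
    percent_of_site = num_or_na(raw[[cols[["percent_of_site"]]]]))
  unknown_tab <- table(raw_region[unknown])
  report <- new_load_report(
    "bioregions", nrow(out),
    unknown_regions = tibble::tibble(value = names(unknown_tab),
                                     n = as.integer(unknown_tab)))
  attr(out, "report") <- report
  out
}

#' Write loaded tables back to CSV in the canonical layout
#'
#' Writing then re-reading a loaded table with the matching `canonical`
#' schema yields an identical record collection (round-trip property).
#'
#' @param x A loaded tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(x, path) {
  readr::write_csv(
    tibble::tibble(SITECODE = x$site_code, SITETYPE = x$site_type,
                   AREAHA = x$total_area_ha, COUNTRY_CODE = x$country),
    path, na = "")
  invisible(path)
}

#' @rdname write_sites
#' @export
write_habitats <- function(x, path) {
  code <- ifelse(x$priority, paste0(x$habitat_code, "*"), x$habitat_code)
  readr::write_csv(
    tibble::tibble(SITECODE = x$site_code, HABITATCODE = code,
                   COVER_HA = x$cover_ha),
    path, na = "")
  invisible(path)
}

#' @rdname write_sites
#' @export
write_bioregions <- function(x, path) {
  readr::write_csv(
    tibble::tibble(SITECODE = x$site_code, BIOGEFRAPHICREG = x$region,
                   PERCENTAGE = x$percent_of_site),
    path, na = "")
  invisible(path)
}
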