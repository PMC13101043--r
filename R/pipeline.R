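#' Run the full representation analysis end to end
#'
#' Loads (or accepts in-memory) the three database tables, curates them,
#' attaches habitat classifications and region assignments, infers natural
#' ranges from the Red List crosswalk, and computes every summary:
#' class coverage, freshwater group shares, nutrient summary, size
#' distributions, per-habitat statistics, freshwater site counts and the
#' biogeographic gap analysis. Deterministic given its inputs.
#'
#' @param sites,habitats,bioregions Tibbles as returned by the readers, or
#'   paths to CSV files (read with the default schemas).
#' @param taxonomy Taxonomy table ([read_taxonomy()]).
#' @param crosswalk Red List crosswalk ([read_crosswalk()]).
#' @param overrides Region override table ([read_overrides()]).
#' @param config Curation thresholds ([curation_config()]).
#' @param min_region_fraction Region-assignment threshold (70).
#' @param options Range-inference options ([range_options()]).
#' @return A list of class `n2k_report`: `coverage`, `group_shares`,
#'   `nutrient`, `size_all`, `size_freshwater`, `habitat_stats`,
#'   `freshwater_sites`, `gap`, `audit`, `classified` (the annotated
#'   dataset), `n_corrected_zero`, `region_na_fw_entries`. Empty but valid
#'   inputs give an empty report (`NULL` summaries, zero counts) rather
#'   than an error.
#' @export
#' @examples
#' fx <- make_worked_fixture()
#' rep <- run_pipeline(fx$sites, fx$habitats, fx$bioregions)
#' rep$coverage$mapped_percent
run_pipeline <- function(sites, habitats, bioregions,
                         taxonomy = read_taxonomy(),
                         crosswalk = read_crosswalk(),
                         overrides = read_overrides(),
                         config = curation_config(),
                         min_region_fraction = 70,
                         options = range_options()) {
  if (is.character(sites)) sites <- read_sites(sites)
  if (is.character(habitats)) habitats <- read_habitats(habitats)
  if (is.character(bioregions)) bioregions <- read_bioregions(bioregions)

  # network area before designation-type pruning (denominator for the
  # whole-network freshwater share): sites passing the area filter only
  network_area <- sum(
    sites$total_area_ha[!is.na(sites$total_area_ha) &
                        sites$total_area_ha >= config$min_area_ha])

  curated <- curate(sites, habitats, config)
  classified <- attach_classifications(curated, taxonomy)

  corrected <- correct_zero_percents(bioregions, overrides)
  assignments <- assign_regions(corrected$bioregions, min_region_fraction,
                                mode = "terrestrial6")
  extended <- assign_regions(corrected$bioregions, min_region_fraction,
                             mode = "extended")
  classified <- attach_regions(classified, assignments)

  empty <- nrow(classified$sites) == 0
  fw_codes <- unique(fw_entries(classified)$habitat_code)
  ranges <- infer_ranges(fw_codes, crosswalk, options)

  report <- list(
    coverage = if (empty) NULL else
      class_coverage(classified, total_network_area_ha = network_area),
    group_shares = if (empty) NULL else group_shares(classified),
    nutrient = if (empty) NULL else nutrient_summary(classified),
    size_all = if (empty) NULL else size_distribution(classified),
    size_freshwater = if (empty) NULL else
      size_distribution(classified, habitat_class = "FRESHWATER"),
    habitat_stats = if (empty) NULL else habitat_stats(classified),
    freshwater_sites = if (empty) NULL else sites_with_freshwater(classified),
    gap = if (empty) NULL else
      gap_analysis(classified, ranges, extended_assignments = extended),
    audit = classified$audit,
    classified = classified,
    n_corrected_zero = corrected$n_corrected,
    region_na_fw_entries = classified$region_na_entries,
    network_area_ha = network_area)
  class(report) <- "n2k_report"
  report
}

#' @export
print.n2k_report <- function(x, ...) {
  cat("<n2k_report>\n")
  print(x$audit$stages)
  if (!is.null(x$coverage)) {
    cat(sprintf("mapped %.1f%%; freshwater %.1f%% of HD area\n",
                x$coverage$mapped_percent,
                x$coverage$class_percent$percent[
                  x$coverage$class_percent$habitat_class == "FRESHWATER"]))
  }
  invisible(x)
}

#' Write a report bundle to CSV files and a JSON summary
#'
#' Re-running the pipeline on identical inputs and writing again produces
#' byte-identical files.
#'
#' @param report An `n2k_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "n2k_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(dir, name))
  }
  w(report$group_shares, "group_shares.csv")
  w(report$nutrient, "nutrient_summary.csv")
  w(report$size_all, "size_distribution_all.csv")
  w(report$size_freshwater, "size_distribution_freshwater.csv")
  w(report$habitat_stats, "habitat_stats.csv")
  w(report$audit$stages, "audit_stages.csv")
  w(report$audit$drops, "audit_drops.csv")
  if (!is.null(report$gap)) {
    gap_flat <- report$gap$table |>
      dplyr::mutate(
        observed_regions = vapply(.data$observed_regions, paste,
                                  character(1), collapse = ";"),
        natural_range = vapply(.data$natural_range, paste, character(1),
                               collapse = ";"))
    readr::write_csv(gap_flat, file.path(dir, "gap_analysis.csv"))
    readr::write_csv(report$gap$tallies, file.path(dir, "gap_tallies.csv"))
  }
  summary <- list(
    stages = report$audit$stages,
    n_corrected_zero = report$n_corrected_zero,
    region_na_fw_entries = report$region_na_fw_entries,
    network_area_ha = report$network_area_ha,
    coverage = if (is.null(report$coverage)) NULL else list(
      total_hd_area_ha = report$coverage$total_hd_area_ha,
      mapped_percent = report$coverage$mapped_percent,
      unmapped_percent = report$coverage$unmapped_percent,
      class_percent = report$coverage$class_percent,
      freshwater_percent_of_network =
        report$coverage$freshwater_percent_of_network))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Per-site report document
#'
#' The document a site-centric front end renders: site metadata plus the
#' site's habitat entries grouped by habitat class, each with cover in
#' hectares and as per cent of the site area.
#'
#' @param classified An `n2k_classified` dataset.
#' @param site_code One site code.
#' @return A list: `site_code`, `site_type`, `total_area_ha`, `country`,
#'   `habitat_classes` (named list of row lists). Unknown codes return a
#'   list with `found = FALSE`.
#' @export
export_site_json <- function(classified, site_code) {
  stopifnot(inherits(classified, "n2k_classified"))
  i <- match(site_code, classified$sites$site_code)
  if (is.na(i)) {
    return(list(found = FALSE, site_code = site_code))
  }
  site <- classified$sites[i, ]
  entries <- classified$entries[classified$entries$site_code == site_code, ,
                                drop = FALSE]
  by_class <- split(entries, entries$habitat_class)
  habitat_classes <- lapply(by_class, function(df) {
    lapply(seq_len(nrow(df)), function(j) list(
      habitat_code = df$habitat_code[j],
      priority = df$priority[j],
      cover_ha = df$cover_ha[j],
      percent_of_site = 100 * df$cover_ha[j] / site$total_area_ha,
      freshwater_group = df$freshwater_group[j],
      nutrient = df$nutrient[j]))
  })
  list(found = TRUE,
       site_code = site$site_code,
       site_type = site$site_type,
       total_area_ha = site$total_area_ha,
       country = site$country,
       n_habitats = nrow(entries),
       habitat_classes = habitat_classes)
}
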