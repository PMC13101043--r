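#' Curation thresholds
#'
#' @param min_area_ha Smallest area (hectares) treated as real; sites or
#'   habitat entries with missing area or area strictly below this are
#'   removed (equality keeps). Default 0.0001 ha = 1 m2.
#' @param max_habitat_sum_percent Sites whose habitat covers sum to strictly
#'   more than this percentage of the site's total area are removed as
#'   inconsistent. Default 100.01.
#' @param drop_bd_only Remove sites designated only under the Birds
#'   Directive (SPAs that do not overlap any SCI/SAC); Annex I habitats are
#'   not part of their designation. Default `TRUE`.
#' @return A list of class `n2k_curation_config`.
#' @export
curation_config <- function(min_area_ha = 1e-4,
                            max_habitat_sum_percent = 100.01,
                            drop_bd_only = TRUE) {
  stopifnot(min_area_ha > 0, max_habitat_sum_percent >= 100)
  structure(list(min_area_ha = min_area_ha,
                 max_habitat_sum_percent = max_habitat_sum_percent,
                 drop_bd_only = drop_bd_only),
            class = "n2k_curation_config")
}

new_audit <- function() {
  structure(list(
    stages = tibble::tibble(stage = character(), unit = character(),
                            n_in = integer(), n_dropped = integer(),
                            n_out = integer()),
    drops = tibble::tibble(stage = character(), site_code = character(),
                           habitat_code = character(), reason = character())),
    class = "n2k_audit")
}

add_stage <- function(audit, stage, unit, n_in, dropped) {
  audit$stages <- dplyr::bind_rows(audit$stages, tibble::tibble(
    stage = stage, unit = unit, n_in = as.integer(n_in),
    n_dropped = nrow(dropped), n_out = as.integer(n_in) - nrow(dropped)))
  if (nrow(dropped) > 0) {
    if (!"habitat_code" %in% names(dropped)) dropped$habitat_code <- NA_character_
    audit$drops <- dplyr::bind_rows(
      audit$drops,
      tibble::tibble(stage = stage, site_code = dropped$site_code,
                     habitat_code = dropped$habitat_code,
                     reason = dropped$reason))
  }
  audit
}

#' @export
print.n2k_audit <- function(x, ...) {
  cat("<n2k_audit>", nrow(x$stages), "stages,", nrow(x$drops),
      "dropped records\n")
  print(x$stages)
  invisible(x)
}

#' Remove sites with missing or negligible total area
#'
#' @param sites A loaded sites tibble.
#' @param config A [curation_config()].
#' @param audit An existing `n2k_audit` to append to (a fresh one by
#'   default).
#' @return A list with `sites` (retained rows) and `audit`. The comparison
#'   is strict: areas exactly equal to `min_area_ha` are kept.
#' @export
filter_sites <- function(sites, config = curation_config(),
                         audit = new_audit()) {
  drop <- is.na(sites$total_area_ha) | sites$total_area_ha < config$min_area_ha
  dropped <- tibble::tibble(
    site_code = sites$site_code[drop],
    reason = ifelse(is.na(sites$total_area_ha[drop]), "missing_site_area",
                    "tiny_site_area"))
  audit <- add_stage(audit, "sites_area", "sites", nrow(sites), dropped)
  list(sites = sites[!drop, , drop = FALSE], audit = audit)
}

#' Remove habitat entries with missing or negligible cover
#'
#' @param entries A loaded habitats tibble (cover in hectares).
#' @inheritParams filter_sites
#' @return A list with `entries` and `audit`; strict `<` as in
#'   [filter_sites()].
#' @export
filter_habitat_entries <- function(entries, config = curation_config(),
                                   audit = new_audit()) {
  drop <- is.na(entries$cover_ha) | entries$cover_ha < config$min_area_ha
  dropped <- tibble::tibble(
    site_code = entries$site_code[drop],
    habitat_code = entries$habitat_code[drop],
    reason = ifelse(is.na(entries$cover_ha[drop]), "missing_cover",
                    "tiny_cover"))
  audit <- add_stage(audit, "entries_cover", "entries", nrow(entries), dropped)
  list(entries = entries[!drop, , drop = FALSE], audit = audit)
}

#' Join filtered sites and entries and apply the site-level exclusions
#'
#' In order: (a) entries whose site is absent from the filtered site table
#' are dropped (orphans); (b) sites whose total area is zero are dropped
#' defensively (the habitat-sum percentage is undefined); (c) sites whose
#' habitat covers sum to more than `max_habitat_sum_percent` of the site
#' area are dropped with all their entries; (d) sites designated only under
#' the Birds Directive are dropped with all their entries. Sites with zero
#' habitat entries are retained: area not mapped as protected habitats is
#' part of the analysis.
#'
#' The habitat-sum percentage is rounded to 6 decimals before comparison so
#' floating-point representation noise cannot flip verdicts at the 100.01
#' boundary; the comparison itself is strict (`>` drops, equality keeps).
#'
#' @param sites Filtered sites (from [filter_sites()]).
#' @param entries Filtered entries (from [filter_habitat_entries()]).
#' @inheritParams filter_sites
#' @return A list of class `n2k_curated` with `sites`, `entries`, `audit`.
#' @export
join_and_prune <- function(sites, entries, config = curation_config(),
                           audit = new_audit()) {
  # duplicate (site, habitat) pairs would break uniqueness downstream: keep
  # the summed cover, one row per pair
  if (anyDuplicated(entries[c("site_code", "habitat_code")]) > 0) {
    entries <- entries |>
      dplyr::group_by(.data$site_code, .data$habitat_code) |>
      dplyr::summarise(priority = any(.data$priority),
                       cover_ha = sum(.data$cover_ha), .groups = "drop")
  }

  orphan <- !(entries$site_code %in% sites$site_code)
  audit <- add_stage(audit, "entries_orphan_site", "entries", nrow(entries),
                     tibble::tibble(site_code = entries$site_code[orphan],
                                    habitat_code = entries$habitat_code[orphan],
                                    reason = "site_not_retained"))
  entries <- entries[!orphan, , drop = FALSE]

  zero <- sites$total_area_ha == 0
  audit <- add_stage(audit, "sites_zero_area", "sites", nrow(sites),
                     tibble::tibble(site_code = sites$site_code[zero],
                                    reason = "zero_area_undefined_percent"))
  sites <- sites[!zero, , drop = FALSE]

  sums <- entries |>
    dplyr::group_by(.data$site_code) |>
    dplyr::summarise(habitat_area = sum(.data$cover_ha), .groups = "drop")
  sites <- dplyr::left_join(sites, sums, by = "site_code")
  sites$habitat_area[is.na(sites$habitat_area)] <- 0
  pct <- round(100 * sites$habitat_area / sites$total_area_ha, 6)
  over <- pct > config$max_habitat_sum_percent
  audit <- add_stage(audit, "sites_overfilled", "sites", nrow(sites),
                     tibble::tibble(site_code = sites$site_code[over],
                                    reason = "habitat_sum_over_limit"))
  sites <- sites[!over, , drop = FALSE]
  dropped_entries <- entries[!(entries$site_code %in% sites$site_code), ,
                             drop = FALSE]
  audit <- add_stage(audit, "entries_overfilled_sites", "entries",
                     nrow(entries),
                     tibble::tibble(site_code = dropped_entries$site_code,
                                    habitat_code = dropped_entries$habitat_code,
                                    reason = "habitat_sum_over_limit"))
  entries <- entries[entries$site_code %in% sites$site_code, , drop = FALSE]

  if (isTRUE(config$drop_bd_only)) {
    bd <- !is.na(sites$site_type) & sites$site_type == "BD_ONLY"
    audit <- add_stage(audit, "sites_bd_only", "sites", nrow(sites),
                       tibble::tibble(site_code = sites$site_code[bd],
                                      reason = "bd_only_designation"))
    sites <- sites[!bd, , drop = FALSE]
    dropped_entries <- entries[!(entries$site_code %in% sites$site_code), ,
                               drop = FALSE]
    audit <- add_stage(audit, "entries_bd_only_sites", "entries",
                       nrow(entries),
                       tibble::tibble(
                         site_code = dropped_entries$site_code,
                         habitat_code = dropped_entries$habitat_code,
                         reason = "bd_only_designation"))
    entries <- entries[entries$site_code %in% sites$site_code, , drop = FALSE]
  }

  sites$habitat_area <- NULL
  structure(list(sites = sites, entries = entries, audit = audit),
            class = "n2k_curated")
}

#' Run the full curation sequence
#'
#' Filters sites, filters habitat entries, then joins and prunes — in that
#' fixed order. Applying the join-stage rules before entry filtering could
#' change the habitat-sum verdicts, so the order is part of the method.
#'
#' @param sites,entries Loaded tables.
#' @inheritParams filter_sites
#' @return An `n2k_curated` list: `sites`, `entries`, `audit`.
#' @export
#' @examples
#' fx <- make_worked_fixture()
#' cur <- curate(fx$sites, fx$habitats)
#' cur$audit$stages
curate <- function(sites, entries, config = curation_config()) {
  s <- filter_sites(sites, config)
  e <- filter_habitat_entries(entries, config, audit = s$audit)
  join_and_prune(s$sites, e$entries, config, audit = e$audit)
}

#' @export
print.n2k_curated <- function(x, ...) {
  cat("<n2k_curated>", nrow(x$sites), "sites,", nrow(x$entries),
      "habitat entries\n")
  invisible(x)
}

#' Export the curation audit
#'
#' @param curated An `n2k_curated` (or `n2k_classified`) object.
#' @param drops_path,stages_path Optional CSV paths; written when given.
#' @return A list with `stages` and `drops` tibbles, invisibly when writing.
#' @export
export_audit <- function(curated, drops_path = NULL, stages_path = NULL) {
  audit <- curated$audit
  if (!is.null(drops_path)) readr::write_csv(audit$drops, drops_path)
  if (!is.null(stages_path)) readr::write_csv(audit$stages, stages_path)
  list(stages = audit$stages, drops = audit$drops)
}
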