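hd_sites <- function(classified) {
  s <- classified$sites
  s[is.na(s$site_type) | s$site_type != "BD_ONLY", , drop = FALSE]
}

#' Coverage of protected habitat classes
#'
#' Percentages of mapped and unmapped area and the per-class split, all
#' over the total area of sites designated under the Habitats Directive
#' (HD-only plus both-directive sites) — the denominator the per-class
#' figures use. When the total network area (including Birds
#' Directive-only sites, which curation removes) is supplied, the
#' freshwater share of the whole network is reported as well.
#'
#' @param classified An `n2k_classified` dataset.
#' @param total_network_area_ha Optional total network area in hectares
#'   including BD-only sites.
#' @return A list of class `n2k_coverage`: `total_hd_area_ha`,
#'   `mapped_percent`, `unmapped_percent`, `class_percent` (tibble
#'   `habitat_class`, `area_ha`, `percent`),
#'   `freshwater_percent_of_network` (or `NA`).
#' @export
class_coverage <- function(classified, total_network_area_ha = NULL) {
  stopifnot(inherits(classified, "n2k_classified"))
  sites <- hd_sites(classified)
  total <- sum(sites$total_area_ha)
  if (!isTRUE(total > 0)) stop("total HD-designated area is zero",
                               call. = FALSE)
  entries <- classified$entries[classified$entries$site_code %in%
                                sites$site_code, , drop = FALSE]
  mapped <- sum(entries$cover_ha)
  by_class <- entries |>
    dplyr::filter(!is.na(.data$habitat_class)) |>
    dplyr::group_by(habitat_class = .data$habitat_class) |>
    dplyr::summarise(area_ha = sum(.data$cover_ha), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(habitat_class = habitat_classes),
                      by = "habitat_class") |>
    dplyr::mutate(area_ha = ifelse(is.na(.data$area_ha), 0, .data$area_ha),
                  percent = 100 * .data$area_ha / total)
  fw_area <- by_class$area_ha[by_class$habitat_class == "FRESHWATER"]
  structure(list(
    total_hd_area_ha = total,
    mapped_percent = 100 * mapped / total,
    unmapped_percent = 100 * (total - mapped) / total,
    class_percent = by_class,
    freshwater_percent_of_network = if (is.null(total_network_area_ha)) {
      NA_real_
    } else 100 * fw_area / total_network_area_ha),
    class = "n2k_coverage")
}

#' @export
print.n2k_coverage <- function(x, ...) {
  cat(sprintf("<n2k_coverage> HD area %.1f ha; mapped %.1f%% / unmapped %.1f%%\n",
              x$total_hd_area_ha, x$mapped_percent, x$unmapped_percent))
  print(x$class_percent)
  invisible(x)
}

fw_entries <- function(classified) {
  e <- classified$entries
  e[!is.na(e$habitat_class) & e$habitat_class == "FRESHWATER", ,
    drop = FALSE]
}

#' Area shares of the five freshwater habitat groups
#'
#' @param classified An `n2k_classified` dataset.
#' @return A tibble `freshwater_group`, `area_ha`, `percent` (of total
#'   freshwater habitat area), `n_sites` (distinct sites); all five groups
#'   always present, zeros included.
#' @export
group_shares <- function(classified) {
  fw <- fw_entries(classified)
  total <- sum(fw$cover_ha)
  fw |>
    dplyr::group_by(freshwater_group = .data$freshwater_group) |>
    dplyr::summarise(area_ha = sum(.data$cover_ha),
                     n_sites = dplyr::n_distinct(.data$site_code),
                     .groups = "drop") |>
    dplyr::right_join(tibble::tibble(freshwater_group = freshwater_groups),
                      by = "freshwater_group") |>
    dplyr::mutate(
      area_ha = ifelse(is.na(.data$area_ha), 0, .data$area_ha),
      n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites),
      percent = if (total > 0) 100 * .data$area_ha / total else 0) |>
    dplyr::arrange(.data$freshwater_group)
}

#' Nutrient-level summary of freshwater habitats
#'
#' Site counts record (site, nutrient) presence: a site hosting habitats of
#' two nutrient classes contributes to both counters. Area percentages are
#' shares of total freshwater habitat area.
#'
#' @param classified An `n2k_classified` dataset.
#' @return A tibble `nutrient`, `n_sites`, `area_ha`, `area_percent`.
#' @export
nutrient_summary <- function(classified) {
  fw <- fw_entries(classified)
  total <- sum(fw$cover_ha)
  fw |>
    dplyr::group_by(nutrient = .data$nutrient) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site_code),
                     area_ha = sum(.data$cover_ha), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(nutrient = nutrient_levels),
                      by = "nutrient") |>
    dplyr::mutate(
      n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites),
      area_ha = ifelse(is.na(.data$area_ha), 0, .data$area_ha),
      area_percent = if (total > 0) 100 * .data$area_ha / total else 0)
}

#' Site size-class distribution
#'
#' Sites are binned into half-open area classes `[0, b1), [b1, b2), ...,
#' [bk, Inf)`. With the default breaks, the classes are below 50 ha, 50 to
#' 500 ha, and 500 ha or more. Optionally restricted to sites holding at
#' least one habitat of a given class.
#'
#' @param classified An `n2k_classified` dataset.
#' @param breaks Increasing positive break points in hectares.
#' @param habitat_class Optional class filter (`"FRESHWATER"`,
#'   `"MARINE_COASTAL"`, `"TERRESTRIAL"`).
#' @return A tibble `size_class`, `n_sites`, `percent`; counts sum to the
#'   number of sites considered.
#' @export
size_distribution <- function(classified, breaks = c(50, 500),
                              habitat_class = NULL) {
  stopifnot(all(diff(breaks) > 0), all(breaks > 0))
  sites <- hd_sites(classified)
  if (!is.null(habitat_class)) {
    keep <- classified$entries$site_code[
      !is.na(classified$entries$habitat_class) &
      classified$entries$habitat_class == habitat_class]
    sites <- sites[sites$site_code %in% keep, , drop = FALSE]
  }
  edges <- c(0, breaks, Inf)
  labels <- character(length(edges) - 1)
  for (i in seq_along(labels)) {
    labels[i] <- if (is.infinite(edges[i + 1])) {
      sprintf(">=%g", edges[i])
    } else sprintf("[%g,%g)", edges[i], edges[i + 1])
  }
  bin <- cut(sites$total_area_ha, breaks = edges, labels = labels,
             right = FALSE, include.lowest = FALSE)
  tab <- table(bin)
  n <- nrow(sites)
  tibble::tibble(size_class = labels,
                 n_sites = as.integer(tab[labels]),
                 percent = if (n > 0) 100 * as.integer(tab[labels]) / n
                           else 0)
}

#' Per-habitat area and site-count statistics (freshwater habitats)
#'
#' @param classified An `n2k_classified` dataset.
#' @return A tibble `habitat_code`, `total_area_ha`, `percent` (of total
#'   freshwater area), `n_sites` (distinct sites), `freshwater_group`,
#'   `nutrient`, sorted by decreasing area.
#' @export
habitat_stats <- function(classified) {
  fw <- fw_entries(classified)
  total <- sum(fw$cover_ha)
  fw |>
    dplyr::group_by(habitat_code = .data$habitat_code) |>
    dplyr::summarise(total_area_ha = sum(.data$cover_ha),
                     n_sites = dplyr::n_distinct(.data$site_code),
                     freshwater_group = dplyr::first(.data$freshwater_group),
                     nutrient = dplyr::first(.data$nutrient),
                     .groups = "drop") |>
    dplyr::mutate(percent = if (total > 0) {
      100 * .data$total_area_ha / total
    } else 0) |>
    dplyr::arrange(dplyr::desc(.data$total_area_ha))
}

#' Sites holding at least one freshwater habitat
#'
#' @param classified An `n2k_classified` dataset.
#' @return A list: `n_sites`, `per_site` (tibble `site_code`,
#'   `n_habitat_types`), `percent_1_to_4` (share of those sites holding one
#'   to four freshwater habitat types).
#' @export
sites_with_freshwater <- function(classified) {
  fw <- fw_entries(classified)
  per_site <- fw |>
    dplyr::group_by(site_code = .data$site_code) |>
    dplyr::summarise(n_habitat_types = dplyr::n_distinct(.data$habitat_code),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_habitat_types))
  n <- nrow(per_site)
  list(n_sites = n,
       per_site = per_site,
       percent_1_to_4 = if (n > 0) {
         100 * mean(per_site$n_habitat_types <= 4)
       } else 0)
}

#' Biogeographic representation-gap analysis
#'
#' For every freshwater habitat present in the network, the set of
#' terrestrial regions where it is designated (entries whose site resolved
#' to a region; NA-region entries are excluded here) is compared with its
#' inferred natural range. The representation proportion is
#' `|observed AND natural| / |natural|`; a habitat is fully represented
#' when its natural range is a subset of the observed set. Habitats with
#' an empty natural range (no usable crosslink) are excluded from the
#' tallies and reported. When extended-mode assignments are supplied, the
#' descriptive count of regions over the full 14-region list is added —
#' this is a different quantity and deliberately a separate column.
#'
#' @param classified An `n2k_classified` dataset carrying regions
#'   (see [attach_regions()]).
#' @param ranges Output of [infer_ranges()] covering the dataset's
#'   freshwater codes.
#' @param extended_assignments Optional [assign_regions()] output in
#'   `"extended"` mode, for the descriptive region counts.
#' @return A list of class `n2k_gap`: `table` (tibble `habitat_code`,
#'   `freshwater_group`, `observed_regions` and `natural_range` list
#'   columns, `n_observed`, `n_natural`, `n_observed_extended`,
#'   `proportion`, `fully_represented`), `tallies` (per freshwater group:
#'   `n_full`, `n_total`), `excluded` (codes without usable crosslink).
#' @export
gap_analysis <- function(classified, ranges, extended_assignments = NULL) {
  stopifnot(inherits(classified, "n2k_classified"))
  if (!"region" %in% names(classified$entries)) {
    stop("dataset carries no region assignments; run attach_regions() first",
         call. = FALSE)
  }
  fw <- fw_entries(classified)
  obs <- fw |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(habitat_code = .data$habitat_code) |>
    dplyr::summarise(observed_regions = list(sort(unique(.data$region))),
                     .groups = "drop")
  codes <- fw |>
    dplyr::distinct(habitat_code = .data$habitat_code,
                    freshwater_group = .data$freshwater_group)
  tab <- codes |>
    dplyr::left_join(obs, by = "habitat_code") |>
    dplyr::left_join(ranges, by = "habitat_code")
  tab$observed_regions <- lapply(tab$observed_regions,
                                 function(s) if (is.null(s)) character(0) else s)
  tab$natural_range <- lapply(tab$natural_range,
                              function(s) if (is.null(s)) character(0) else s)
  tab$no_crosslink[is.na(tab$no_crosslink)] <- TRUE
  tab$n_observed <- lengths(tab$observed_regions)
  tab$n_natural <- lengths(tab$natural_range)

  if (!is.null(extended_assignments)) {
    ext <- fw
    idx <- match(ext$site_code, extended_assignments$site_code)
    ext$ext_region <- extended_assignments$region[idx]
    ext_counts <- ext |>
      dplyr::filter(!is.na(.data$ext_region)) |>
      dplyr::group_by(habitat_code = .data$habitat_code) |>
      dplyr::summarise(n_observed_extended =
                         dplyr::n_distinct(.data$ext_region),
                       .groups = "drop")
    tab <- dplyr::left_join(tab, ext_counts, by = "habitat_code")
    tab$n_observed_extended[is.na(tab$n_observed_extended)] <- 0L
  } else {
    tab$n_observed_extended <- NA_integer_
  }

  tab$proportion <- mapply(function(o, nat) {
    if (length(nat) == 0) return(NA_real_)
    length(intersect(o, nat)) / length(nat)
  }, tab$observed_regions, tab$natural_range)
  tab$fully_represented <- mapply(function(o, nat) {
    if (length(nat) == 0) return(NA)
    all(nat %in% o)
  }, tab$observed_regions, tab$natural_range)

  excluded <- tab$habitat_code[tab$n_natural == 0]
  usable <- tab[tab$n_natural > 0, , drop = FALSE]
  tallies <- usable |>
    dplyr::group_by(freshwater_group = .data$freshwater_group) |>
    dplyr::summarise(n_full = sum(.data$fully_represented),
                     n_total = dplyr::n(), .groups = "drop")
  structure(list(table = tab, tallies = tallies, excluded = excluded),
            class = "n2k_gap")
}

#' @export
print.n2k_gap <- function(x, ...) {
  cat("<n2k_gap>", nrow(x$table), "habitats;",
      sum(x$table$fully_represented, na.rm = TRUE), "fully represented\n")
  print(x$tallies)
  invisible(x)
}
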