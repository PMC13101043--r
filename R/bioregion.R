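#' Read the region-assignment override table
#'
#' Overrides replace the recorded percentage for one (site, region) pair,
#' taking precedence over the automatic zero-percent correction. The
#' shipped default contains the one documented case, BE2200036, whose
#' Atlantic share is set to 79 (the remainder of the site lies in the
#' Continental region).
#'
#' @param path CSV with columns `site_code`, `region`, `percent`.
#' @return A tibble.
#' @export
read_overrides <- function(path = n2k_extdata("bioregion_overrides.csv")) {
  x <- readr::read_csv(path, col_types = readr::cols(
    site_code = readr::col_character(), region = readr::col_character(),
    percent = readr::col_double()), progress = FALSE, show_col_types = FALSE)
  stopifnot(all(x$percent > 0 & x$percent <= 100))
  x
}

#' Correct sole-region zero percentages
#'
#' Some sites lying entirely within one region are recorded with 0% instead
#' of 100%. The deterministic rule replacing the original visual
#' inspection: a site whose region records consist of exactly one distinct
#' region whose (summed) percentage is 0 has that percentage set to 100,
#' unless an override specifies a different value. Sites with several
#' regions are left untouched (the ambiguity cannot be resolved from the
#' table alone).
#'
#' @param bioregions A loaded bioregions tibble.
#' @param overrides Override table from [read_overrides()].
#' @return A list: `bioregions` (corrected, with a `rule` column noting
#'   `CORRECTED_0_TO_100` / `OVERRIDE` where applied), `n_corrected`,
#'   `log` (tibble of corrected site codes).
#' @export
correct_zero_percents <- function(bioregions, overrides = read_overrides()) {
  x <- bioregions
  x$rule <- NA_character_

  # apply overrides first; overridden sites are exempt from the 0->100 rule
  if (nrow(overrides) > 0) {
    key <- paste(x$site_code, x$region)
    okey <- paste(overrides$site_code, overrides$region)
    hit <- match(key, okey)
    x$percent_of_site[!is.na(hit)] <- overrides$percent[hit[!is.na(hit)]]
    x$rule[!is.na(hit)] <- "OVERRIDE"
  }

  per_site <- x |>
    dplyr::group_by(.data$site_code) |>
    dplyr::summarise(n_regions = dplyr::n_distinct(.data$region),
                     total_pct = sum(.data$percent_of_site, na.rm = TRUE),
                     .groups = "drop")
  sole_zero <- per_site$site_code[per_site$n_regions == 1 &
                                  per_site$total_pct == 0]
  sole_zero <- setdiff(sole_zero, overrides$site_code)
  fix <- x$site_code %in% sole_zero
  x$percent_of_site[fix] <- 100
  x$rule[fix] <- "CORRECTED_0_TO_100"
  list(bioregions = x, n_corrected = length(sole_zero),
       log = tibble::tibble(site_code = sole_zero))
}

#' Assign each site at most one biogeographic region
#'
#' A site is assigned the region holding at least `min_fraction` per cent of
#' its area (rule `GE70` at the default threshold); failing that, the
#' region whose reported percentage equals 100 (rule `MAX100`, which covers
#' the corrected zero-percent sites); otherwise the site is unresolved
#' (`NA_UNRESOLVED`). Duplicate (site, region) rows are summed before
#' evaluation. In terrestrial mode only the six main terrestrial regions
#' qualify: a site lying 80% in the Marine Baltic region resolves to `NA`.
#' Two regions both reporting 100 is a data error and resolves to `NA`.
#'
#' @param bioregions Corrected bioregions (from [correct_zero_percents()]).
#' @param min_fraction Minimum percentage for a direct assignment (70).
#' @param mode `"terrestrial6"` restricts candidate regions to the six main
#'   terrestrial regions (gap analysis); `"extended"` admits all 14 regions
#'   (descriptive counts).
#' @return A tibble `site_code`, `region` (NA when unresolved),
#'   `rule_used` in `{GE70, MAX100, CORRECTED_0_TO_100, OVERRIDE,
#'   NA_UNRESOLVED}`; correction provenance wins over the generic rule
#'   label.
#' @export
assign_regions <- function(bioregions, min_fraction = 70,
                           mode = c("terrestrial6", "extended")) {
  mode <- match.arg(mode)
  candidates <- if (mode == "terrestrial6") n2k_regions("terrestrial6")
                else n2k_regions("extended")
  if (!"rule" %in% names(bioregions)) bioregions$rule <- NA_character_

  summed <- bioregions |>
    dplyr::group_by(.data$site_code, .data$region) |>
    dplyr::summarise(percent = sum(.data$percent_of_site, na.rm = TRUE),
                     corrected = any(!is.na(.data$rule)),
                     corr_rule = dplyr::first(stats::na.omit(.data$rule)),
                     .groups = "drop")

  assign_one <- function(df) {
    cand <- df[df$region %in% candidates, , drop = FALSE]
    pick <- NULL
    rule <- "NA_UNRESOLVED"
    if (nrow(cand) > 0) {
      if (max(cand$percent) == 100) {
        at_max <- cand[cand$percent == 100, , drop = FALSE]
        if (nrow(at_max) == 1) {       # two regions both at 100: data error
          pick <- at_max
          rule <- "MAX100"
        }
      } else if (any(cand$percent >= min_fraction)) {
        pick <- cand[which.max(cand$percent), ]
        rule <- "GE70"
      }
    }
    if (is.null(pick)) {
      return(tibble::tibble(region = NA_character_,
                            rule_used = "NA_UNRESOLVED"))
    }
    if (isTRUE(pick$corrected)) rule <- pick$corr_rule
    tibble::tibble(region = pick$region, rule_used = rule)
  }

  summed |>
    dplyr::group_by(.data$site_code) |>
    dplyr::group_modify(~ assign_one(.x)) |>
    dplyr::ungroup()
}

#' Attach region assignments to a classified dataset
#'
#' Every habitat entry receives its site's assigned region, or `NA` when
#' the site is unresolved or absent from the assignment table. NA-region
#' entries stay in the dataset — they are excluded from per-region tallies
#' only, not from area or count totals.
#'
#' @param classified An `n2k_classified` object.
#' @param assignments Output of [assign_regions()].
#' @return The classified object with an entry column `region` and a
#'   `region_na_entries` count (freshwater entries without a region).
#' @export
attach_regions <- function(classified, assignments) {
  stopifnot(inherits(classified, "n2k_classified"))
  idx <- match(classified$entries$site_code, assignments$site_code)
  classified$entries$region <- assignments$region[idx]
  classified$region_assignments <- assignments
  fw <- classified$entries$habitat_class == "FRESHWATER"
  classified$region_na_entries <-
    sum(fw & is.na(classified$entries$region), na.rm = TRUE)
  classified
}
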