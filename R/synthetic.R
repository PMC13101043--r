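#' Configuration for the synthetic Natura 2000 generator
#'
#' Defaults emulate the 2021 database's shape at configurable size:
#' log-normally distributed site areas clamped to at least 1 ha, a
#' site-type mix dominated by Habitats Directive designations, a Poisson
#' number of habitat entries per site drawn from the shipped Annex I code
#' pool (freshwater codes upweighted), habitat covers allocated as random
#' fractions of the site area summing below 100%, and anomaly classes at
#' roughly the frequencies the real database exhibits: missing or
#' negligible site areas, missing or negligible covers, habitat sums
#' exceeding the site area, region percentages recorded as 0, and sites
#' spanning several regions.
#'
#' @param n_sites Number of sites.
#' @param site_type_mix Probabilities over `BD_ONLY`, `HD_ONLY`, `BOTH`.
#' @param area_meanlog,area_sdlog Log-normal parameters of site area (ha).
#' @param habitats_per_site_lambda Poisson mean of habitat entries per site
#'   (zero entries allowed: unmapped sites are part of the data model).
#' @param habitat_pool Character vector of Annex I codes to draw from
#'   (default: all codes in the shipped taxonomy).
#' @param freshwater_weight Sampling weight of freshwater codes relative to
#'   other codes.
#' @param anomaly_rates Named numeric vector with entries
#'   `missing_site_area`, `tiny_site_area`, `overfilled_site`,
#'   `zero_percent_region`, `multi_region_site` (site-level, disjoint: at
#'   most one per site) and `missing_cover`, `tiny_cover` (entry-level,
#'   planted only on sites without a site-level anomaly and not BD-only, so
#'   planted counts add up stage by stage).
#' @param region_mix Named probabilities over the 14-region vocabulary for
#'   the single region of non-anomalous sites.
#' @param seed Integer seed; identical configuration and seed give
#'   identical tables.
#' @return A list of class `n2k_synth_config`.
#' @export
synth_config <- function(
    n_sites = 1000,
    site_type_mix = c(BD_ONLY = 0.17, HD_ONLY = 0.48, BOTH = 0.35),
    area_meanlog = log(120), area_sdlog = 1.9,
    habitats_per_site_lambda = 4,
    habitat_pool = NULL,
    freshwater_weight = 2,
    anomaly_rates = c(missing_site_area = 0.003, tiny_site_area = 0.001,
                      overfilled_site = 0.02, zero_percent_region = 0.015,
                      multi_region_site = 0.08, missing_cover = 0.04,
                      tiny_cover = 0.005),
    region_mix = c(Alpine = 0.12, Atlantic = 0.18, Boreal = 0.15,
                   Continental = 0.25, Mediterranean = 0.15,
                   Pannonian = 0.05, BlackSea = 0.01, Macaronesian = 0.005,
                   Steppic = 0.01, MarineAtlantic = 0.02,
                   MarineBaltic = 0.02, MarineBlackSea = 0.01,
                   MarineMacaronesian = 0.005, MarineMediterranean = 0.02),
    seed = 1L) {
  defaults <- c(missing_site_area = 0, tiny_site_area = 0,
                overfilled_site = 0, zero_percent_region = 0,
                multi_region_site = 0, missing_cover = 0, tiny_cover = 0)
  defaults[names(anomaly_rates)] <- anomaly_rates
  anomaly_rates <- defaults
  stopifnot(n_sites >= 1,
            abs(sum(site_type_mix) - 1) < 1e-8,
            abs(sum(region_mix) - 1) < 1e-8,
            all(anomaly_rates >= 0 & anomaly_rates <= 1),
            sum(anomaly_rates[c("missing_site_area", "tiny_site_area",
                                "overfilled_site", "zero_percent_region",
                                "multi_region_site")]) <= 1)
  if (anomaly_rates[["overfilled_site"]] > 0 &&
      habitats_per_site_lambda <= 0) {
    stop("overfilled_site anomalies need sites with habitats ",
         "(habitats_per_site_lambda must be > 0)", call. = FALSE)
  }
  structure(list(
    n_sites = as.integer(n_sites), site_type_mix = site_type_mix,
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    habitats_per_site_lambda = habitats_per_site_lambda,
    habitat_pool = habitat_pool, freshwater_weight = freshwater_weight,
    anomaly_rates = anomaly_rates, region_mix = region_mix,
    seed = as.integer(seed)), class = "n2k_synth_config")
}

with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic Natura 2000 dataset with known ground truth
#'
#' Produces the three tables in the same layout as [read_sites()],
#' [read_habitats()] and [read_bioregions()] return, plus a ground-truth
#' list derived by construction: anomalies are planted disjointly, so their
#' counts are known without re-detection, and every expected post-curation
#' quantity is bookkeeping over the planted labels, not a re-run of the
#' pipeline.
#'
#' @param config A [synth_config()].
#' @param taxonomy Taxonomy used for the code pool and the truth's class
#'   areas (default: shipped table).
#' @return A list: `sites`, `habitats`, `bioregions` (tibbles) and `truth`
#'   (list; see Details in the vignette).
#' @export
#' @examples
#' g <- generate_n2k(synth_config(n_sites = 50, seed = 7))
#' g$truth$expected_sites
generate_n2k <- function(config = synth_config(),
                         taxonomy = read_taxonomy()) {
  stopifnot(inherits(config, "n2k_synth_config"))
  with_preserved_seed(config$seed, {
    n <- config$n_sites
    rates <- config$anomaly_rates
    site_code <- sprintf("SY%07d", seq_len(n))
    site_type <- sample(names(config$site_type_mix), n, replace = TRUE,
                        prob = config$site_type_mix)
    area <- pmax(stats::rlnorm(n, config$area_meanlog, config$area_sdlog), 1)

    site_classes <- c("missing_site_area", "tiny_site_area",
                      "overfilled_site", "zero_percent_region",
                      "multi_region_site")
    p <- rates[site_classes]
    anomaly <- sample(c(site_classes, "none"), n, replace = TRUE,
                      prob = c(p, 1 - sum(p)))

    n_hab <- stats::rpois(n, config$habitats_per_site_lambda)
    n_hab[anomaly == "overfilled_site" & n_hab == 0] <- 1L

    pool <- config$habitat_pool
    if (is.null(pool)) pool <- taxonomy$habitat_code
    pool_w <- ifelse(
      taxonomy$habitat_class[match(pool, taxonomy$habitat_code)] ==
        "FRESHWATER",
      config$freshwater_weight, 1)
    pool_w[is.na(pool_w)] <- 1

    # habitat entries: covers are fractions of the (pre-anomaly) site area
    code_list <- lapply(seq_len(n), function(i) {
      if (n_hab[i] == 0) return(character(0))
      sample(pool, min(n_hab[i], length(pool)), prob = pool_w)
    })
    site_idx <- rep(seq_len(n), lengths(code_list))
    codes <- unlist(code_list)
    frac_total <- ifelse(anomaly == "overfilled_site",
                         stats::runif(n, 1.05, 1.8),
                         stats::runif(n, 0.05, 0.95))
    w <- stats::rexp(length(codes)) + 1e-9
    cover <- numeric(length(codes))
    for (i in unique(site_idx)) {
      sel <- site_idx == i
      cover[sel] <- pmax(frac_total[i] * area[i] * w[sel] / sum(w[sel]),
                         2e-4)
    }

    entries <- tibble::tibble(
      site_code = site_code[site_idx],
      habitat_code = codes,
      priority = FALSE,
      cover_ha = cover)

    # entry-level anomalies only on clean, non-BD sites (additive truth)
    clean_entry <- anomaly[site_idx] == "none" &
      site_type[site_idx] != "BD_ONLY"
    u <- stats::runif(nrow(entries))
    make_missing <- clean_entry & u < rates[["missing_cover"]]
    make_tiny <- clean_entry & !make_missing &
      u < rates[["missing_cover"]] + rates[["tiny_cover"]]
    entries$cover_ha[make_missing] <- NA_real_
    entries$cover_ha[make_tiny] <- stats::runif(sum(make_tiny), 1e-7, 9e-5)

    # site-area anomalies applied after covers were allocated
    area_out <- area
    area_out[anomaly == "missing_site_area"] <- NA_real_
    area_out[anomaly == "tiny_site_area"] <-
      stats::runif(sum(anomaly == "tiny_site_area"), 1e-7, 9e-5)

    sites <- tibble::tibble(site_code = site_code, site_type = site_type,
                            total_area_ha = area_out,
                            country = "SY")

    # bioregion table
    six <- n2k_regions("terrestrial6")
    mix6 <- config$region_mix[six] / sum(config$region_mix[six])
    region1 <- character(n)
    bior <- vector("list", n)
    for (i in seq_len(n)) {
      if (anomaly[i] == "zero_percent_region") {
        r <- sample(six, 1, prob = mix6)
        bior[[i]] <- tibble::tibble(site_code = site_code[i], region = r,
                                    percent_of_site = 0)
        region1[i] <- r
      } else if (anomaly[i] == "multi_region_site") {
        rr <- sample(six, 2, prob = mix6)
        bior[[i]] <- tibble::tibble(site_code = site_code[i], region = rr,
                                    percent_of_site = c(55, 45))
        region1[i] <- NA_character_
      } else {
        r <- sample(names(config$region_mix), 1, prob = config$region_mix)
        bior[[i]] <- tibble::tibble(site_code = site_code[i], region = r,
                                    percent_of_site = 100)
        region1[i] <- if (r %in% six) r else NA_character_
      }
    }
    bioregions <- dplyr::bind_rows(bior)

    # ---- ground truth by construction -------------------------------------
    dropped_area <- anomaly %in% c("missing_site_area", "tiny_site_area")
    dropped_over <- anomaly == "overfilled_site"
    dropped_bd <- site_type == "BD_ONLY" & !dropped_area & !dropped_over
    retained <- !dropped_area & !dropped_over & !dropped_bd

    entry_site_retained <- retained[site_idx]
    entry_dropped_cover <- make_missing | make_tiny
    entry_retained <- entry_site_retained & !entry_dropped_cover

    ret_entries <- entries[entry_retained, , drop = FALSE]
    cls <- taxonomy$habitat_class[match(ret_entries$habitat_code,
                                        taxonomy$habitat_code)]
    class_area <- vapply(
      c("FRESHWATER", "MARINE_COASTAL", "TERRESTRIAL"),
      function(k) sum(ret_entries$cover_ha[cls == k]), numeric(1))

    fw_ret <- ret_entries[cls == "FRESHWATER", , drop = FALSE]
    fw_region <- region1[match(fw_ret$site_code, site_code)]

    obs_regions <- split(fw_region[!is.na(fw_region)],
                         fw_ret$habitat_code[!is.na(fw_region)])
    obs_regions <- lapply(obs_regions, function(x) sort(unique(x)))

    truth <- list(
      n_sites_raw = n,
      n_entries_raw = nrow(entries),
      drops = c(
        sites_area = sum(dropped_area),
        entries_cover = sum(entry_dropped_cover),
        entries_orphan_site = sum(dropped_area[site_idx] &
                                    !entry_dropped_cover),
        sites_overfilled = sum(dropped_over),
        entries_overfilled_sites = sum(dropped_over[site_idx] &
                                         !entry_dropped_cover),
        sites_bd_only = sum(dropped_bd),
        entries_bd_only_sites = sum(dropped_bd[site_idx] &
                                      !entry_dropped_cover)),
      expected_sites = sum(retained),
      expected_entries = nrow(ret_entries),
      expected_corrected_zero = sum(anomaly == "zero_percent_region"),
      expected_region_na_sites = sum(retained & is.na(region1)),
      expected_region_na_fw_entries = sum(is.na(fw_region)),
      class_area = class_area,
      habitat_sites = vapply(
        split(ret_entries$site_code, ret_entries$habitat_code),
        function(x) length(unique(x)), integer(1)),
      observed_regions = obs_regions)
    list(sites = sites, habitats = entries, bioregions = bioregions,
         truth = truth)
  })
}

#' Miniature hand-built dataset exercising every curation rule
#'
#' Six sites: a multi-habitat freshwater site (Continental), a site whose
#' sole region is recorded as 0% (corrected to Atlantic), a Birds
#' Directive-only site (removed), an overfilled site whose habitat covers
#' sum to 150% of its area (removed), an unresolved 50/50 two-region site,
#' and a site with one terrestrial habitat plus a negligible freshwater
#' entry (entry removed). Expected values for every summary are hand
#' computations stored alongside the tables.
#'
#' @return A list: `sites`, `habitats`, `bioregions`, `expected`.
#' @export
make_worked_fixture <- function() {
  sites <- tibble::tibble(
    site_code = c("FX000001", "FX000002", "FX000003", "FX000004",
                  "FX000005", "FX000006"),
    site_type = c("BOTH", "HD_ONLY", "BD_ONLY", "HD_ONLY", "HD_ONLY",
                  "HD_ONLY"),
    total_area_ha = c(100, 50, 200, 10, 80, 40),
    country = c("DE", "BE", "FR", "PL", "SE", "ES"))
  habitats <- tibble::tibble(
    site_code = c("FX000001", "FX000001", "FX000002", "FX000003",
                  "FX000004", "FX000004", "FX000005", "FX000006",
                  "FX000006"),
    habitat_code = c("3150", "7140", "91E0", "3260", "3150", "6430",
                     "7110", "8210", "3170"),
    priority = FALSE,
    cover_ha = c(20, 30, 10, 5, 9, 6, 40, 5, 5e-5))
  bioregions <- tibble::tibble(
    site_code = c("FX000001", "FX000002", "FX000003", "FX000004",
                  "FX000005", "FX000005", "FX000006"),
    region = c("Continental", "Atlantic", "Atlantic", "Continental",
               "Alpine", "Boreal", "Mediterranean"),
    percent_of_site = c(100, 0, 100, 100, 50, 50, 85))
  expected <- list(
    sites_retained = 4L,                  # FX1, FX2, FX5, FX6
    entries_retained = 5L,                # 3150+7140, 91E0, 7110, 8210
    total_hd_area_ha = 270,               # 100 + 50 + 80 + 40
    mapped_area_ha = 105,                 # 20+30+10+40+5
    mapped_percent = 100 * 105 / 270,
    unmapped_percent = 100 * 165 / 270,
    class_area = c(FRESHWATER = 100, MARINE_COASTAL = 0, TERRESTRIAL = 5),
    freshwater_percent = 100 * 100 / 270,
    network_area_ha = 480,                # post area-filter, incl. BD-only
    freshwater_percent_of_network = 100 * 100 / 480,
    group_area = c(RUNNING = 0, STANDING = 20, PEATLAND = 70, FOREST = 10,
                   GRASS_HEATH_COASTAL = 0),
    nutrient_area = c(OLIGOTROPHIC = 40, MESOTROPHIC = 30, EUTROPHIC = 30),
    nutrient_sites = c(OLIGOTROPHIC = 1L, MESOTROPHIC = 1L, EUTROPHIC = 2L),
    size_counts = c(1L, 3L, 0L),          # [0,50): FX6; [50,500): rest
    n_sites_with_freshwater = 3L,         # FX1, FX2, FX5
    n_corrected_zero = 1L,                # FX2
    region_na_fw_entries = 1L,            # FX5's 7110
    regions = c(FX000001 = "Continental", FX000002 = "Atlantic",
                FX000005 = NA, FX000006 = "Mediterranean"))
  list(sites = sites, habitats = habitats, bioregions = bioregions,
       expected = expected)
}

#' Brute-force natural-range oracle
#'
#' An intentionally naive reference for the range-union inference: it
#' re-reads the crosswalk CSVs with base R and accumulates the union with
#' explicit loops, sharing no code with [infer_range()]. Used in tests as
#' the independent check; slow and per-code on purpose.
#'
#' @param annex_code One Annex I code.
#' @param links_path,regions_path,aggregated_path CSV paths (defaults:
#'   shipped tables).
#' @param include_low_importance,strict,baltic_codes As in
#'   [range_options()].
#' @return Sorted character vector of regions.
#' @export
range_union_oracle <- function(
    annex_code,
    links_path = n2k_extdata("rl_crosswalk_synthetic.csv"),
    regions_path = n2k_extdata("rl_regions_synthetic.csv"),
    aggregated_path = n2k_extdata("rl_aggregated_synthetic.csv"),
    include_low_importance = TRUE, strict = FALSE, baltic_codes = "1650") {
  six <- c("Alpine", "Atlantic", "Boreal", "Continental", "Mediterranean",
           "Pannonian")
  code <- toupper(sub("\\*$", "", trimws(annex_code)))
  agg <- utils::read.csv(aggregated_path, colClasses = "character")
  acc <- character(0)
  hit_agg <- FALSE
  for (i in seq_len(nrow(agg))) {
    if (toupper(agg$annex_code[i]) == code) {
      hit_agg <- TRUE
      for (r in strsplit(agg$regions[i], ";")[[1]]) {
        r <- trimws(r)
        if (r %in% six && !(r %in% acc)) acc <- c(acc, r)
      }
    }
  }
  if (!hit_agg) {
    links <- utils::read.csv(links_path, colClasses = "character")
    regs <- utils::read.csv(regions_path, colClasses = "character")
    for (i in seq_len(nrow(links))) {
      if (toupper(links$annex_code[i]) != code) next
      if (links$include[i] != "1") next
      rel <- links$relation[i]
      if (strict && !(rel %in% c("same", "close"))) next
      if (!include_low_importance && rel == "low_importance") next
      set <- NULL
      for (j in seq_len(nrow(regs))) {
        if (regs$rl_code[j] == links$rl_code[i]) set <- regs$regions[j]
      }
      if (is.null(set)) next
      parts <- if (toupper(set) == "UNSPECIFIED") six
               else trimws(strsplit(set, ";")[[1]])
      for (r in parts) {
        if (r %in% six && !(r %in% acc)) acc <- c(acc, r)
      }
    }
  }
  if (code %in% baltic_codes) {
    for (r in c("Boreal", "Continental")) if (!(r %in% acc)) acc <- c(acc, r)
  }
  sort(acc)
}
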