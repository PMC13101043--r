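no_anomalies <- c(missing_site_area = 0, tiny_site_area = 0,
                  overfilled_site = 0, zero_percent_region = 0,
                  multi_region_site = 0, missing_cover = 0, tiny_cover = 0)

# independent bookkeeping check: run the real pipeline and compare every
# planted count with the generator's ground truth
expect_truth_agreement <- function(g) {
  cur <- curate(g$sites, g$habitats)
  stages <- stats::setNames(cur$audit$stages$n_dropped,
                            cur$audit$stages$stage)
  for (s in names(g$truth$drops)) {
    expect_equal(unname(stages[s]), unname(g$truth$drops[[s]]), info = s)
  }
  expect_equal(nrow(cur$sites), g$truth$expected_sites)
  expect_equal(nrow(cur$entries), g$truth$expected_entries)

  cls <- attach_classifications(cur)
  areas <- vapply(
    c("FRESHWATER", "MARINE_COASTAL", "TERRESTRIAL"),
    function(k) sum(cls$entries$cover_ha[cls$entries$habitat_class == k]),
    numeric(1))
  expect_equal(areas, g$truth$class_area)

  corrected <- correct_zero_percents(g$bioregions,
                                     overrides = read_overrides()[0, ])
  expect_equal(corrected$n_corrected, g$truth$expected_corrected_zero)
  cls <- attach_regions(cls, assign_regions(corrected$bioregions))
  expect_equal(cls$region_na_entries, g$truth$expected_region_na_fw_entries)

  counts <- habitat_stats(cls)
  fw_truth <- g$truth$habitat_sites[counts$habitat_code]
  expect_equal(unname(counts$n_sites), unname(as.integer(fw_truth)))
  invisible(cls)
}

test_that("identical configuration and seed give identical tables", {
  cfg <- synth_config(n_sites = 80, seed = 99)
  g1 <- generate_n2k(cfg)
  g2 <- generate_n2k(cfg)
  expect_identical(g1, g2)
  g3 <- generate_n2k(synth_config(n_sites = 80, seed = 100))
  expect_false(identical(g1$sites, g3$sites))
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(555)
  a <- stats::runif(1)
  set.seed(555)
  invisible(generate_n2k(synth_config(n_sites = 20, seed = 1)))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("with all anomaly rates zero curation drops only BD-only sites", {
  g <- generate_n2k(synth_config(n_sites = 200, seed = 5,
                                 anomaly_rates = no_anomalies))
  cur <- curate(g$sites, g$habitats)
  drops <- cur$audit$stages
  non_bd <- drops[!grepl("bd_only", drops$stage), ]
  expect_equal(sum(non_bd$n_dropped), 0L)
  expect_truth_agreement(g)
  # and with BD-only sites excluded from the mix, nothing drops at all
  g2 <- generate_n2k(synth_config(
    n_sites = 150, seed = 5, anomaly_rates = no_anomalies,
    site_type_mix = c(BD_ONLY = 0, HD_ONLY = 0.6, BOTH = 0.4)))
  cur2 <- curate(g2$sites, g2$habitats)
  expect_equal(sum(cur2$audit$stages$n_dropped), 0L)
  expect_equal(nrow(cur2$sites), 150L)
})

test_that("planted missing-area sites equal the first curation stage's drops", {
  g <- generate_n2k(synth_config(
    n_sites = 1000, seed = 1,
    anomaly_rates = c(missing_site_area = 0.1)))
  n_planted <- sum(is.na(g$sites$total_area_ha))
  expect_gt(n_planted, 50)
  cur <- curate(g$sites, g$habitats)
  expect_equal(cur$audit$stages$n_dropped[
    cur$audit$stages$stage == "sites_area"], n_planted)
  expect_equal(unname(g$truth$drops[["sites_area"]]), n_planted)
})

test_that("pipeline counts equal planted ground truth across seeds and rate mixes", {
  rate_settings <- list(
    c(missing_site_area = 0.05, tiny_site_area = 0, overfilled_site = 0,
      zero_percent_region = 0, multi_region_site = 0, missing_cover = 0,
      tiny_cover = 0),
    c(missing_site_area = 0, tiny_site_area = 0.05, overfilled_site = 0.1,
      zero_percent_region = 0, multi_region_site = 0, missing_cover = 0,
      tiny_cover = 0),
    c(missing_site_area = 0, tiny_site_area = 0, overfilled_site = 0,
      zero_percent_region = 0.1, multi_region_site = 0.2,
      missing_cover = 0, tiny_cover = 0),
    c(missing_site_area = 0, tiny_site_area = 0, overfilled_site = 0,
      zero_percent_region = 0, multi_region_site = 0, missing_cover = 0.15,
      tiny_cover = 0.05),
    c(missing_site_area = 0.03, tiny_site_area = 0.01,
      overfilled_site = 0.05, zero_percent_region = 0.05,
      multi_region_site = 0.1, missing_cover = 0.08, tiny_cover = 0.02))
  for (i in seq_along(rate_settings)) {
    g <- generate_n2k(synth_config(n_sites = 150, seed = 100 + i,
                                   anomaly_rates = rate_settings[[i]]))
    expect_truth_agreement(g)
  }
})

test_that("planted gap structure matches the pipeline's observed regions", {
  g <- generate_n2k(synth_config(n_sites = 250, seed = 42))
  cls <- expect_truth_agreement(g)
  cw <- read_crosswalk()
  fw_codes <- unique(cls$entries$habitat_code[
    cls$entries$habitat_class == "FRESHWATER"])
  gap <- gap_analysis(cls, infer_ranges(fw_codes, cw))
  for (j in seq_len(nrow(gap$table))) {
    code <- gap$table$habitat_code[j]
    planted <- g$truth$observed_regions[[code]]
    if (is.null(planted)) planted <- character(0)
    expect_equal(gap$table$observed_regions[[j]], planted, info = code)
  }
})

test_that("overfilled-site drops are binomially dispersed across seeds", {
  r <- 0.1
  n <- 60
  drops <- vapply(1:24, function(seed) {
    g <- generate_n2k(synth_config(
      n_sites = n, seed = seed,
      anomaly_rates = c(missing_site_area = 0, tiny_site_area = 0,
                        overfilled_site = r, zero_percent_region = 0,
                        multi_region_site = 0, missing_cover = 0,
                        tiny_cover = 0)))
    unname(g$truth$drops[["sites_overfilled"]])
  }, numeric(1))
  # loose sanity: mean within 4 binomial SDs, spread not degenerate
  expect_lt(abs(mean(drops) - n * r), 4 * sqrt(n * r * (1 - r) / 24))
  expect_gt(stats::var(drops), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(habitats_per_site_lambda = 0,
                            anomaly_rates = c(overfilled_site = 0.1)),
               "overfilled")
  expect_error(synth_config(site_type_mix = c(BD_ONLY = 0.5, HD_ONLY = 0.2,
                                              BOTH = 0.2)))
})

test_that("the worked fixture is internally consistent with its documentation", {
  fx <- make_worked_fixture()
  expect_equal(nrow(fx$sites), 6)
  expect_equal(sum(fx$sites$site_type == "BD_ONLY"), 1)
  # one overfilled site: FX000004 at 150%
  sums <- tapply(fx$habitats$cover_ha, fx$habitats$site_code, sum)
  pct <- 100 * sums[fx$sites$site_code] / fx$sites$total_area_ha
  expect_equal(sum(pct > 100.01, na.rm = TRUE), 1)
  # one sole-region 0% site and one 50/50 site
  expect_equal(sum(fx$bioregions$percent_of_site == 0), 1)
})
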