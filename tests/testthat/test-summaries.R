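classified_fixture <- function() {
  fx <- make_worked_fixture()
  cls <- attach_classifications(curate(fx$sites, fx$habitats))
  corrected <- correct_zero_percents(fx$bioregions,
                                     overrides = read_overrides()[0, ])
  attach_regions(cls, assign_regions(corrected$bioregions))
}

test_that("class coverage reproduces the fixture's hand arithmetic", {
  fx <- make_worked_fixture()
  cov <- class_coverage(classified_fixture(),
                        total_network_area_ha = fx$expected$network_area_ha)
  expect_equal(cov$total_hd_area_ha, fx$expected$total_hd_area_ha)
  expect_equal(cov$mapped_percent, fx$expected$mapped_percent)
  expect_equal(cov$unmapped_percent, fx$expected$unmapped_percent)
  expect_equal(cov$mapped_percent + cov$unmapped_percent, 100)
  got <- stats::setNames(cov$class_percent$area_ha,
                         cov$class_percent$habitat_class)
  expect_equal(got[names(fx$expected$class_area)], fx$expected$class_area)
  expect_equal(sum(cov$class_percent$percent), cov$mapped_percent)
  expect_equal(cov$freshwater_percent_of_network,
               fx$expected$freshwater_percent_of_network)
})

test_that("a single fully covered freshwater site gives 100% mapped", {
  sites <- mk_sites(site_code = "A", total_area_ha = 100)
  entries <- mk_entries(site_code = "A", habitat_code = "3150",
                        cover_ha = 100)
  cls <- attach_classifications(curate(sites, entries))
  cov <- class_coverage(cls)
  expect_equal(cov$mapped_percent, 100)
  expect_equal(cov$unmapped_percent, 0)
  expect_equal(
    cov$class_percent$percent[cov$class_percent$habitat_class ==
                                "FRESHWATER"], 100)
})

test_that("two half-empty sites: one 30-ha terrestrial habitat is 15% mapped", {
  sites <- mk_sites(site_code = c("A", "B"), total_area_ha = c(100, 100))
  entries <- mk_entries(site_code = "A", habitat_code = "8210",
                        cover_ha = 30)
  cov <- class_coverage(attach_classifications(curate(sites, entries)))
  expect_equal(cov$mapped_percent, 15)
  expect_equal(
    cov$class_percent$percent[cov$class_percent$habitat_class ==
                                "TERRESTRIAL"], 15)
})

test_that("coverage errors on zero total area", {
  cls <- attach_classifications(
    curate(mk_sites(site_code = character(0), total_area_ha = numeric(0)),
           mk_entries(site_code = character(0),
                      habitat_code = character(0), cover_ha = numeric(0))))
  expect_error(class_coverage(cls), "zero")
})

test_that("group shares cover the five groups and match planted areas", {
  fx <- make_worked_fixture()
  gs <- group_shares(classified_fixture())
  expect_equal(nrow(gs), 5)
  got <- stats::setNames(gs$area_ha, gs$freshwater_group)
  expect_equal(got[names(fx$expected$group_area)], fx$expected$group_area)
  expect_equal(sum(gs$percent), 100, tolerance = 1e-9)
})

test_that("nutrient summary counts (site, nutrient) presence and area shares", {
  fx <- make_worked_fixture()
  ns <- nutrient_summary(classified_fixture())
  got_area <- stats::setNames(ns$area_ha, ns$nutrient)
  got_sites <- stats::setNames(ns$n_sites, ns$nutrient)
  expect_equal(got_area[names(fx$expected$nutrient_area)],
               fx$expected$nutrient_area)
  expect_equal(got_sites[names(fx$expected$nutrient_sites)],
               fx$expected$nutrient_sites)
  expect_equal(sum(ns$area_percent), 100, tolerance = 1e-9)
  # one site hosting two nutrient classes contributes to both counters
  sites <- mk_sites(site_code = "A", total_area_ha = 100)
  entries <- mk_entries(site_code = c("A", "A"),
                        habitat_code = c("7110", "3150"),
                        cover_ha = c(10, 10))
  ns2 <- nutrient_summary(attach_classifications(curate(sites, entries)))
  expect_equal(sum(ns2$n_sites), 2L)
})

test_that("size classes are half-open with the boundary in the upper class", {
  sites <- mk_sites(site_code = c("A", "B", "C"),
                    total_area_ha = c(49.99, 50, 500))
  entries <- mk_entries(site_code = "A", habitat_code = "3150",
                        cover_ha = 1)
  sd <- size_distribution(attach_classifications(curate(sites, entries)))
  expect_equal(sd$n_sites, c(1L, 1L, 1L))
  expect_equal(sum(sd$n_sites), 3L)
  expect_equal(sum(sd$percent), 100)
})

test_that("size distribution restricted to a habitat class filters sites", {
  fx <- make_worked_fixture()
  sd <- size_distribution(classified_fixture(),
                          habitat_class = "FRESHWATER")
  expect_equal(sum(sd$n_sites), fx$expected$n_sites_with_freshwater)
})

test_that("habitat statistics aggregate area and distinct sites per code", {
  st <- habitat_stats(classified_fixture())
  row <- st[st$habitat_code == "7110", ]
  expect_equal(row$total_area_ha, 40)
  expect_equal(row$percent, 40)
  expect_equal(row$n_sites, 1L)
  expect_equal(sum(st$percent), 100, tolerance = 1e-9)
  # one habitat across 3 sites, 10 ha each
  sites <- mk_sites(site_code = c("A", "B", "C"),
                    total_area_ha = rep(100, 3))
  entries <- mk_entries(site_code = c("A", "B", "C"),
                        habitat_code = "3260", cover_ha = rep(10, 3))
  st2 <- habitat_stats(attach_classifications(curate(sites, entries)))
  expect_equal(st2$total_area_ha, 30)
  expect_equal(st2$percent, 100)
  expect_equal(st2$n_sites, 3L)
})

test_that("removing one habitat removes exactly its row and keeps other areas", {
  g <- generate_n2k(synth_config(n_sites = 200, seed = 13))
  cls <- attach_classifications(curate(g$sites, g$habitats))
  st <- habitat_stats(cls)
  victim <- st$habitat_code[1]
  cls2 <- cls
  cls2$entries <- cls2$entries[cls2$entries$habitat_code != victim, ]
  st2 <- habitat_stats(cls2)
  expect_equal(nrow(st2), nrow(st) - 1)
  merged <- dplyr::inner_join(st, st2, by = "habitat_code")
  expect_equal(merged$total_area_ha.x, merged$total_area_ha.y)
})

test_that("freshwater site census counts sites and type multiplicity", {
  fx <- make_worked_fixture()
  fws <- sites_with_freshwater(classified_fixture())
  expect_equal(fws$n_sites, fx$expected$n_sites_with_freshwater)
  expect_equal(fws$per_site$n_habitat_types[
    fws$per_site$site_code == "FX000001"], 2L)
  expect_equal(fws$percent_1_to_4, 100)
  empty <- attach_classifications(
    curate(mk_sites(site_code = "A", total_area_ha = 10),
           mk_entries(site_code = "A", habitat_code = "8210",
                      cover_ha = 1)))
  expect_equal(sites_with_freshwater(empty)$n_sites, 0)
})

test_that("summaries are invariant to entry permutation", {
  g <- generate_n2k(synth_config(n_sites = 150, seed = 21))
  cls <- attach_classifications(curate(g$sites, g$habitats))
  shuf <- cls
  set.seed(2)
  shuf$entries <- shuf$entries[sample(nrow(shuf$entries)), ]
  expect_equal(group_shares(cls), group_shares(shuf))
  expect_equal(nutrient_summary(cls), nutrient_summary(shuf))
  expect_equal(habitat_stats(cls), habitat_stats(shuf))
  expect_equal(class_coverage(cls)$mapped_percent,
               class_coverage(shuf)$mapped_percent)
})

test_that("gap proportions are bounded and equal 1 exactly on subset", {
  cw <- read_crosswalk()
  cls <- classified_fixture()
  ranges <- infer_ranges(unique(cls$entries$habitat_code[
    cls$entries$habitat_class == "FRESHWATER"]), cw)
  gap <- gap_analysis(cls, ranges)
  ok <- !is.na(gap$table$proportion)
  expect_true(all(gap$table$proportion[ok] >= 0 &
                    gap$table$proportion[ok] <= 1))
  expect_equal(gap$table$fully_represented[ok],
               gap$table$proportion[ok] == 1)
  # observed equals natural range -> proportion exactly 1
  obs3150 <- gap$table$observed_regions[[
    which(gap$table$habitat_code == "3150")]]
  expect_equal(obs3150, "Continental")
  # habitat natural {A,B,C,D} observed in 2 of them -> 0.5 (set arithmetic)
  nat <- infer_range("3160", cw)       # 4 regions in the shipped tables
  expect_length(nat, 4)
  sites <- mk_sites(site_code = c("A", "B"), total_area_ha = c(10, 10))
  entries <- mk_entries(site_code = c("A", "B"), habitat_code = "3160",
                        cover_ha = c(1, 1))
  br <- mk_bioregions(site_code = c("A", "B"), region = nat[1:2],
                      percent_of_site = 100)
  cls2 <- attach_regions(attach_classifications(curate(sites, entries)),
                         assign_regions(br))
  gap2 <- gap_analysis(cls2, infer_ranges("3160", cw))
  expect_equal(gap2$table$proportion, 0.5)
  expect_false(gap2$table$fully_represented)
})

test_that("gap analysis separates terrestrial and extended region counts", {
  cw <- read_crosswalk()
  sites <- mk_sites(site_code = c("A", "B"), total_area_ha = c(10, 10))
  entries <- mk_entries(site_code = c("A", "B"), habitat_code = "3160",
                        cover_ha = c(1, 1))
  br <- mk_bioregions(site_code = c("A", "B"),
                      region = c("Boreal", "MarineBaltic"),
                      percent_of_site = 100)
  corrected <- correct_zero_percents(br, overrides = read_overrides()[0, ])
  cls <- attach_regions(attach_classifications(curate(sites, entries)),
                        assign_regions(corrected$bioregions))
  gap <- gap_analysis(cls, infer_ranges("3160", cw),
                      extended_assignments = assign_regions(
                        corrected$bioregions, mode = "extended"))
  expect_equal(gap$table$n_observed, 1L)           # marine never counts here
  expect_equal(gap$table$n_observed_extended, 2L)  # but is described here
})

test_that("habitats without crosslinks are excluded from tallies and reported", {
  sites <- mk_sites(site_code = "A", total_area_ha = 10)
  entries <- mk_entries(site_code = c("A", "A"),
                        habitat_code = c("3160", "3150"),
                        cover_ha = c(1, 1))
  br <- mk_bioregions(site_code = "A", region = "Boreal",
                      percent_of_site = 100)
  cls <- attach_regions(attach_classifications(curate(sites, entries)),
                        assign_regions(br))
  cw <- read_crosswalk()
  ranges <- infer_ranges("3160", cw)     # 3150 deliberately missing
  gap <- gap_analysis(cls, ranges)
  expect_equal(gap$excluded, "3150")
  expect_equal(sum(gap$tallies$n_total), 1L)
})
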