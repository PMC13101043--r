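test_that("sole-region zero percentages are corrected to 100", {
  br <- mk_bioregions(
    site_code = c("BE2200037", "X1", "X1", "X2"),
    region = c("Atlantic", "Alpine", "Continental", "Boreal"),
    percent_of_site = c(0, 0, 60, 100))
  out <- correct_zero_percents(br, overrides = read_overrides()[0, ])
  expect_equal(out$n_corrected, 1)
  expect_equal(out$log$site_code, "BE2200037")
  expect_equal(out$bioregions$percent_of_site[1], 100)
  # two-region site with a 0 stays untouched: not a sole-region case
  expect_equal(out$bioregions$percent_of_site[2], 0)
})

test_that("overrides win over the automatic correction", {
  br <- mk_bioregions(site_code = "BE2200036", region = "Atlantic",
                      percent_of_site = 0)
  out <- correct_zero_percents(br)        # shipped override: Atlantic 79
  expect_equal(out$n_corrected, 0)
  expect_equal(out$bioregions$percent_of_site, 79)
  expect_equal(out$bioregions$rule, "OVERRIDE")
  asg <- assign_regions(out$bioregions)
  expect_equal(asg$region, "Atlantic")    # 79 >= 70
  expect_equal(asg$rule_used, "OVERRIDE")
})

test_that("assignment rules: GE70, MAX100, marine exclusion, ties, duplicates", {
  br <- mk_bioregions(
    site_code = c("A", "A", "B", "B", "C", "D", "E", "E", "F", "F",
                  "G", "G"),
    region = c("Atlantic", "Continental",      # A: 79/21 -> Atlantic
               "Alpine", "Continental",        # B: 50/50 -> NA
               "Boreal",                       # C: 100 -> Boreal
               "MarineBaltic",                 # D: marine 80 -> NA
               "Pannonian", "Pannonian",       # E: duplicates 40+40 -> 80
               "Alpine", "Boreal",             # F: both 100 -> NA (error)
               "Steppic", "Mediterranean"),    # G: non-six 90 / six 10 -> NA
    percent_of_site = c(79, 21, 50, 50, 100, 80, 40, 40, 100, 100, 90, 10))
  asg <- assign_regions(br)
  got <- stats::setNames(asg$region, asg$site_code)
  expect_equal(unname(got[c("A", "C", "E")]),
               c("Atlantic", "Boreal", "Pannonian"))
  expect_true(all(is.na(got[c("B", "D", "F", "G")])))
  rules <- stats::setNames(asg$rule_used, asg$site_code)
  expect_equal(unname(rules[c("A", "C", "E")]), c("GE70", "MAX100", "GE70"))
  expect_true(all(rules[c("B", "D", "F", "G")] == "NA_UNRESOLVED"))
  # invariant: region is NA exactly when the rule is NA_UNRESOLVED
  expect_equal(is.na(asg$region), asg$rule_used == "NA_UNRESOLVED")
})

test_that("extended mode admits marine regions as candidates", {
  br <- mk_bioregions(site_code = "D", region = "MarineBaltic",
                      percent_of_site = 80)
  expect_true(is.na(assign_regions(br)$region))
  expect_equal(assign_regions(br, mode = "extended")$region, "MarineBaltic")
})

test_that("raising the threshold only unresolves, never flips, assignments", {
  set.seed(42)
  sites <- sprintf("P%03d", 1:60)
  br <- dplyr::bind_rows(lapply(sites, function(s) {
    k <- sample(1:3, 1)
    p <- as.numeric(stats::rmultinom(1, 100, rep(1, k)))
    mk_bioregions(site_code = s,
                  region = sample(n2k_regions("extended"), k),
                  percent_of_site = p)
  }))
  lo <- assign_regions(br, min_fraction = 60)
  hi <- assign_regions(br, min_fraction = 85)
  both <- !is.na(lo$region) & !is.na(hi$region)
  expect_true(all(lo$region[both] == hi$region[both]))
  # anything resolved at 85 is resolved at 60
  expect_true(all(!is.na(lo$region[!is.na(hi$region)])))
})

test_that("assignment is independent of record order", {
  br <- mk_bioregions(
    site_code = c("A", "A", "B", "C", "C"),
    region = c("Atlantic", "Continental", "Boreal", "Alpine", "Pannonian"),
    percent_of_site = c(79, 21, 100, 30, 70))
  a1 <- assign_regions(br)
  a2 <- assign_regions(br[rev(seq_len(nrow(br))), ])
  expect_equal(a1, a2)
})

test_that("attaching regions labels freshwater entries and counts NAs", {
  fx <- make_worked_fixture()
  cls <- attach_classifications(curate(fx$sites, fx$habitats))
  corrected <- correct_zero_percents(fx$bioregions,
                                     overrides = read_overrides()[0, ])
  expect_equal(corrected$n_corrected, fx$expected$n_corrected_zero)
  cls <- attach_regions(cls, assign_regions(corrected$bioregions))
  expect_equal(cls$region_na_entries, fx$expected$region_na_fw_entries)
  got <- cls$entries$region[match(c("FX000001", "FX000002", "FX000005"),
                                  cls$entries$site_code)]
  expect_equal(got, c("Continental", "Atlantic", NA))
})

test_that("sites absent from the region table resolve to NA entries", {
  sites <- mk_sites(site_code = c("A", "B", "C", "D", "E"),
                    total_area_ha = rep(100, 5))
  entries <- mk_entries(
    site_code = rep(c("A", "B", "C", "D", "E"), each = 3),
    habitat_code = rep(c("3150", "7110", "3260"), 5),
    cover_ha = rep(1, 15))
  br <- mk_bioregions(site_code = c("A", "B", "C"),
                      region = "Boreal", percent_of_site = 100)
  cls <- attach_classifications(curate(sites, entries))
  cls <- attach_regions(cls, assign_regions(br))
  expect_equal(cls$region_na_entries, 6L)   # 2 sites x 3 entries
})
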