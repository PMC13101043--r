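# in-memory table builders used across tests

mk_sites <- function(...) {
  df <- tibble::tibble(...)
  if (!"site_type" %in% names(df)) df$site_type <- "HD_ONLY"
  if (!"country" %in% names(df)) df$country <- NA_character_
  df[c("site_code", "site_type", "total_area_ha", "country")]
}

mk_entries <- function(...) {
  df <- tibble::tibble(...)
  if (!"priority" %in% names(df)) df$priority <- FALSE
  df[c("site_code", "habitat_code", "priority", "cover_ha")]
}

mk_bioregions <- function(...) {
  tibble::tibble(...)[c("site_code", "region", "percent_of_site")]
}

write_csv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# audit conservation: out = in - dropped at every stage, and the drop log
# partitions the dropped records stage by stage
expect_audit_conserved <- function(audit) {
  expect_equal(audit$stages$n_out, audit$stages$n_in - audit$stages$n_dropped)
  logged <- table(factor(audit$drops$stage, levels = audit$stages$stage))
  expect_equal(as.integer(logged), audit$stages$n_dropped)
}
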