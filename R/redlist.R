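crosswalk_relations <- c("same", "close", "narrower", "wider", "overlap",
                         "low_importance")

#' Read the Annex I / Red List of Habitats crosswalk
#'
#' Two tables drive the natural-range inference: the crosslink table
#' (Annex I code, Red List habitat code, relation category, include flag)
#' and the Red List region table (Red List code, set of the six main
#' terrestrial biogeographic regions it is typical for, or `UNSPECIFIED`
#' when no region is indicated). The shipped files are synthetic stand-ins
#' for the expert crosswalk (see the package vignette); the relation labels
#' accepted are validated against a fixed set but the set itself is data:
#' any label in the file outside the accepted vocabulary is a hard error.
#'
#' @param links_path Crosswalk CSV: `annex_code`, `rl_code`, `relation`,
#'   `include` (0/1).
#' @param regions_path RL region CSV: `rl_code`, `regions`
#'   (semicolon-separated or `"UNSPECIFIED"`).
#' @param aggregated_path Pre-aggregated terrestrial unions for Annex I
#'   codes linked to very many (>20) Red List habitats: `annex_code`,
#'   `regions`.
#' @return A list of class `n2k_crosswalk`: `links`, `rl_regions` (named
#'   list of region-set character vectors, `"UNSPECIFIED"` sentinel kept),
#'   `aggregated` (named list).
#' @export
read_crosswalk <- function(
    links_path = n2k_extdata("rl_crosswalk_synthetic.csv"),
    regions_path = n2k_extdata("rl_regions_synthetic.csv"),
    aggregated_path = n2k_extdata("rl_aggregated_synthetic.csv")) {
  links <- readr::read_csv(links_path, col_types = readr::cols(
    annex_code = readr::col_character(), rl_code = readr::col_character(),
    relation = readr::col_character(), include = readr::col_integer()),
    progress = FALSE, show_col_types = FALSE)
  bad <- !links$relation %in% crosswalk_relations
  if (any(bad)) {
    stop("unknown crosswalk relation label(s): ",
         paste(unique(links$relation[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(links[c("annex_code", "rl_code")]) > 0) {
    stop("duplicate (annex_code, rl_code) pair in crosswalk", call. = FALSE)
  }
  links$annex_code <- normalize_habitat_code(links$annex_code)$code

  reg <- readr::read_csv(regions_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  parse_regions <- function(s) {
    if (is.na(s) || toupper(s) == "UNSPECIFIED") return("UNSPECIFIED")
    out <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    unknown <- setdiff(out, n2k_regions("terrestrial6"))
    if (length(unknown) > 0) {
      stop("RL region table contains region(s) outside the six-region ",
           "vocabulary: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    out
  }
  rl_regions <- stats::setNames(lapply(reg$regions, parse_regions),
                                reg$rl_code)

  agg <- readr::read_csv(aggregated_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    show_col_types = FALSE)
  aggregated <- stats::setNames(lapply(agg$regions, parse_regions),
                                normalize_habitat_code(agg$annex_code)$code)

  structure(list(links = links, rl_regions = rl_regions,
                 aggregated = aggregated),
            class = "n2k_crosswalk")
}

#' Options controlling natural-range inference
#'
#' @param include_low_importance Count low-importance crosslinks toward the
#'   range union (`TRUE`, the inclusive approach; some Red List habitats
#'   lack distribution data otherwise). Turning them off can only shrink
#'   inferred ranges.
#' @param strict Restrict the union to `same` and `close` links only,
#'   bounding the overestimation the inclusive approach accepts.
#' @param baltic_codes Annex I codes of Baltic Sea-associated habitats
#'   whose range always includes the Boreal and Continental regions.
#' @return A list of class `n2k_range_options`.
#' @export
range_options <- function(include_low_importance = TRUE, strict = FALSE,
                          baltic_codes = "1650") {
  structure(list(include_low_importance = include_low_importance,
                 strict = strict, baltic_codes = baltic_codes),
            class = "n2k_range_options")
}

#' Infer a habitat's natural biogeographic range from its Red List links
#'
#' The natural range is the union, over all of the habitat's included
#' crosslinked Red List habitats, of those habitats' terrestrial region
#' sets. A linked Red List habitat with no indicated region
#' (`UNSPECIFIED`) is assumed to occur in all six regions and expands the
#' union accordingly. Codes with a shipped pre-aggregated union (habitats
#' linked to more than 20 Red List habitats, i.e. estuaries and Boreal
#' Baltic inlets) use it directly. Baltic-associated habitats additionally
#' include the Boreal and Continental regions.
#'
#' @param annex_code One normalized Annex I code.
#' @param crosswalk An `n2k_crosswalk` from [read_crosswalk()].
#' @param options An [range_options()] list.
#' @return A character vector (sorted subset of the six terrestrial
#'   regions), or a zero-length vector carrying attribute
#'   `no_crosslink = TRUE` when the code has no usable link.
#' @export
#' @examples
#' cw <- read_crosswalk()
#' infer_range("3120", cw)
infer_range <- function(annex_code, crosswalk, options = range_options()) {
  stopifnot(inherits(crosswalk, "n2k_crosswalk"), length(annex_code) == 1)
  six <- n2k_regions("terrestrial6")

  if (annex_code %in% names(crosswalk$aggregated)) {
    out <- sort(intersect(crosswalk$aggregated[[annex_code]], six))
  } else {
    links <- crosswalk$links[crosswalk$links$annex_code == annex_code &
                             crosswalk$links$include == 1L, , drop = FALSE]
    if (isTRUE(options$strict)) {
      links <- links[links$relation %in% c("same", "close"), , drop = FALSE]
    }
    if (!isTRUE(options$include_low_importance)) {
      links <- links[links$relation != "low_importance", , drop = FALSE]
    }
    if (nrow(links) == 0) {
      out <- character(0)
      attr(out, "no_crosslink") <- TRUE
      return(out)
    }
    sets <- crosswalk$rl_regions[links$rl_code]
    out <- character(0)
    for (s in sets) {
      if (is.null(s)) next
      out <- union(out, if (identical(s, "UNSPECIFIED")) six else s)
    }
    out <- sort(intersect(out, six))
  }
  if (annex_code %in% options$baltic_codes) {
    out <- sort(union(out, c("Boreal", "Continental")))
  }
  if (length(out) == 0) attr(out, "no_crosslink") <- TRUE
  out
}

#' Infer natural ranges for a set of Annex I codes
#'
#' @param annex_codes Character vector of normalized codes.
#' @inheritParams infer_range
#' @return A tibble `habitat_code`, `natural_range` (list column of region
#'   vectors), `n_natural`, `no_crosslink`.
#' @export
infer_ranges <- function(annex_codes, crosswalk, options = range_options()) {
  annex_codes <- unique(annex_codes)
  sets <- lapply(annex_codes, infer_range, crosswalk = crosswalk,
                 options = options)
  tibble::tibble(
    habitat_code = annex_codes,
    natural_range = sets,
    n_natural = lengths(sets),
    no_crosslink = vapply(sets, function(s) isTRUE(attr(s, "no_crosslink")),
                          logical(1)))
}
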