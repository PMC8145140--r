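#' Reference hotspot tables from a disease-mapping case study
#'
#' Published summary tables for 24 circular hotspots detected from roughly
#' 4000 patient residences (oto-laryngo-pharyngeal diagnoses) in the
#' province of Naples, Italy. The underlying patient events were never
#' deposited, so these per-hotspot summaries are the only reproducible
#' quantities of that study and are packaged verbatim as regression
#' fixtures.
#'
#' `naples_hotspots()` returns, for each hotspot, its area in km^2, the
#' standard deviation of the membership degrees, and the entropy-based
#' reliability. Across these 24 hotspots, reliability depends strongly and
#' approximately linearly on the membership fluctuation (R^2 about 0.86)
#' but hardly at all on the area (R^2 about 0.13); see
#' [analyze_reliability()].
#'
#' `naples_expert_labels()` returns the three-class reliability label of
#' each hotspot next to the label independently assigned by a panel of
#' expert physicians. Labels are kept exactly as published: note that
#' hotspot 23 (reliability 0.61) is printed as `Mean` although the stated
#' `> 0.6` rule would make it `High`, and that two reliabilities differ by
#' 0.01 from `naples_hotspots()`; neither is "corrected" here.
#'
#' @return A tibble with 24 rows. `naples_hotspots()`: `id`, `area_km2`,
#'   `membership_std`, `reliability`. `naples_expert_labels()`: `id`,
#'   `reliability`, `reliability_class`, `expert_class`.
#' @examples
#' analyze_reliability(naples_hotspots())
#' with(naples_expert_labels(), agreement_table(reliability_class,
#'                                              expert_class))
#' @export
naples_hotspots <- function() {
  readr::read_csv(
    system.file("extdata", "naples_hotspots.csv", package = "hotspotr",
                mustWork = TRUE),
    col_types = readr::cols(
      id = "i", area_km2 = "d", membership_std = "d", reliability = "d"
    ),
    show_col_types = FALSE
  )
}

#' @rdname naples_hotspots
#' @export
naples_expert_labels <- function() {
  readr::read_csv(
    system.file("extdata", "naples_expert_labels.csv", package = "hotspotr",
                mustWork = TRUE),
    col_types = readr::cols(
      id = "i", reliability = "d",
      reliability_class = "c", expert_class = "c"
    ),
    show_col_types = FALSE
  )
}
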