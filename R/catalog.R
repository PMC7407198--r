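#' The 30-analyte knee-tissue panel catalog
#'
#' Fixed roster of the 9 cytokines and 21 phosphoproteins measured in the
#' periprosthetic tissue panels. Analyte names are stored ASCII-safe (e.g.
#' `p-GSK-3a/b`); [display_name()] maps them to conventional typography
#' (`p-GSK-3α/β`). Row order is the canonical node order used by
#' every downstream table and matrix.
#'
#' @return A tibble with columns `analyte`, `class` (`"cytokine"` or
#'   `"phosphoprotein"`) and `site` (phospho-site label, `NA` for cytokines).
#' @export
#' @examples
#' cat30 <- panel_catalog()
#' table(cat30$class)
panel_catalog <- function() {
  phospho <- tibble::tribble(
    ~analyte,     ~site,
    "p-CREB",     "Ser133",
    "p-HSP27",    "Ser78",
    "p-IkBa",     "Ser32/Ser36",
    "p-MEK1",     "Ser217/Ser221",
    "p-S6RP",     "Ser235/Ser236",
    "p-Smad2",    "Ser465/Ser467",
    "p-Src",      "Tyr416",
    "p-Syk",      "Tyr352",
    "p-c-Jun",    "Ser63",
    "p-AKT",      "Ser473",
    "p-p53",      "Ser15",
    "p-p38",      "Thr180/Tyr182",
    "p-p70S6K",   "Ser380",
    "p-PTEN",     "Ser380",
    "p-ZAP-70",   "Tyr319",
    "p-BAD",      "Ser136",
    "p-ERK1/2",   "Thr202/Tyr204",
    "p-GSK-3a/b", "Ser21/Ser9",
    "p-p90RSK",   "Ser380",
    "p-VEGFR2",   "Tyr1175",
    "p-NF-kB",    "Ser536"
  )
  cyto <- tibble::tibble(
    analyte = c("IL-1b", "IL-4", "IL-6", "IL-1a", "IL-10",
                "IL-12p70", "IL-13", "IFN-y", "TNF-a"),
    site = NA_character_
  )
  dplyr::bind_rows(
    dplyr::mutate(phospho, class = "phosphoprotein"),
    dplyr::mutate(cyto, class = "cytokine")
  )[, c("analyte", "class", "site")]
}

#' Display names for panel analytes
#'
#' Maps ASCII-safe canonical analyte names to their conventional Greek-letter
#' spellings for reports and figures.
#'
#' @param analyte Character vector of canonical analyte names.
#' @return Character vector of display names; unknown names pass through.
#' @export
display_name <- function(analyte) {
  map <- c(
    "p-IkBa"     = "p-IκBα",
    "p-GSK-3a/b" = "p-GSK-3α/β",
    "p-NF-kB"    = "p-NF-κB",
    "IL-1a"      = "IL-1α",
    "IL-1b"      = "IL-1β",
    "IFN-y"      = "IFN-γ",
    "TNF-a"      = "TNF-α"
  )
  out <- unname(map[analyte])
  ifelse(is.na(out), analyte, out)
}

# Design constants: patient groups, tissue depths, anatomical locations.
# PC (posterior capsule) is only collected at the adjacent tissue layer.
GROUPS <- c("primary", "aseptic", "septic")
DEPTHS <- c("ATL", "RTL")
DEPTH_LOCATIONS <- list(
  ATL = c("F", "T", "LG", "PC"),
  RTL = c("F", "T", "LG")
)

#' Valid group, depth, and location labels of the study design
#'
#' @return Named list with `groups`, `depths`, and `depth_locations` (the
#'   anatomical locations sampled at each depth: four at ATL, three at RTL —
#'   the posterior capsule cannot be collected at the radial layer).
#' @export
design_labels <- function() {
  list(groups = GROUPS, depths = DEPTHS, depth_locations = DEPTH_LOCATIONS)
}
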