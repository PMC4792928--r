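#' Reference polygon-class counts for follicular epithelia
#'
#' Published per-class cell counts for wild-type and *RabX1*-mutant
#' Drosophila follicular epithelium, used as the worked example for
#' [shape_summary_from_counts()]: the wild type is dominated by hexagonal
#' cells, while the mutant shows a broadened polygon-class distribution and
#' larger, more variable cell areas.
#'
#' @return named list with one entry per genotype; each entry holds
#'   `counts` (cells per vertex class 4-8), `n`, and the reported area
#'   statistics (`mean_area_um2`, `sd_area_um2`, `n_area`; the area
#'   measurement covered a slightly different cell set than the vertex
#'   classification for the mutant, hence the separate `n_area`).
#' @export
reference_shape_counts <- function() {
  list(
    wild_type = list(
      genotype = "Wild type",
      counts = c("4" = 2, "5" = 46, "6" = 116, "7" = 32, "8" = 0),
      n = 196L,
      mean_area_um2 = 35.7, sd_area_um2 = 11.57, n_area = 196L),
    rabx1 = list(
      genotype = "RabX1",
      counts = c("4" = 23, "5" = 105, "6" = 134, "7" = 73, "8" = 10),
      n = 345L,
      mean_area_um2 = 51.25, sd_area_um2 = 23.66, n_area = 352L)
  )
}
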