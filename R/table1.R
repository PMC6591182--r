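#' Published PAG-cerebellum connectivity density table
#'
#' The packaged reference table of group connectivity densities between the
#' periaqueductal gray (PAG) seed and the 34 cerebellar regions (six deep
#' nuclei, 20 hemispheric lobules, eight vermal lobules), transcribed to two
#' decimals exactly as published: per-pathway group mean volume-normalized
#' density (delta_NORM, percent), between-subject SD (percent), and
#' coefficient of variation (COV = SD / mean). The `hemisphere` and
#' `compartment` columns encode the Stoodley-Schmahmann grouping used for
#' compartment aggregation (anterior, posterior, flocculonodular, nuclear).
#'
#' @return data.frame with 34 rows and columns `structure`, `hemisphere`,
#'   `compartment`, `mean_delta_norm`, `sd`, `cov`.
#' @examples
#' t1 <- load_table1_fixture()
#' subset(t1, structure == "Right fastigial nucleus")
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_connectivity_density.tsv",
                      package = "tractdensity", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 34L)
  df
}
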