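#' Demographic contingency counts of the reference cohort
#'
#' Group-by-category counts for the nine categorical demographic variables
#' of the three-group civilian trauma cohort (17 no-PTSD, 19 full-PTSD,
#' 20 subsyndromal-PTSD participants), shipped as package data. Running
#' [chi_square_independence()] on each variable's table reproduces the
#' published between-group chi-square statistics.
#'
#' @return Named list of group x category count matrices.
#' @export
#' @examples
#' tabs <- demographic_tables()
#' chi_square_independence(tabs$medication)$statistic
demographic_tables <- function() {
  path <- system.file("extdata", "table2_demographics.csv",
                      package = "lkmstates", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$variable), function(d) {
    m <- t(as.matrix(d[, c("nPTSD", "fPTSD", "sPTSD")]))
    colnames(m) <- d$category
    m
  })
  out[unique(df$variable)]
}
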