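#' Fructo-oligosaccharide addition design
#'
#' The 18 reference compositions (samples A-R) of citrus juices -- Valencia
#' orange, mandarin orange, citrus unshiu, white and ruby grapefruit --
#' spiked with 12-30 g/L of two commercial fructo-oligosaccharide
#' formulations, as determined by HPLC. Ships as a packaged fixture and is
#' the concentration design of the FOS-addition study.
#'
#' @return A [concentration_table()] with 18 rows over all six components;
#'   the juice variety of each sample is in attribute `"variety"`.
#' @examples
#' ct <- table1_design()
#' nrow(ct) # 18
#' @export
table1_design <- function() {
  path <- system.file("extdata", "table1_concentrations.csv",
                      package = "ftirsugars", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  ct <- concentration_table(df[, -1])
  attr(ct, "variety") <- stats::setNames(df$variety, df$sample)
  ct
}
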