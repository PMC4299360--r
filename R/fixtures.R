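#' Packaged published count tables
#'
#' Returns one of the published contingency tables shipped with the package
#' as an integer matrix with named dimensions:
#' \describe{
#'   \item{T1}{anterior type (I--V2) x posterior type (a--k), 6 x 11.  The
#'     V2 row is printed ambiguously in the source; the packaged allocation
#'     (d, e, f, g, j) is the unique one whose column sums equal T5.}
#'   \item{T2}{A1 balance x anterior integrity, 2 x 2.}
#'   \item{T3}{side (L/R) x A1 status, 2 x 4.}
#'   \item{T4}{ACoA shape census, 1 x 8 frequency vector.}
#'   \item{T5}{posterior type count vector, 1 x 11.}
#'   \item{T6}{A1 side status x homolateral PCA type among A1-variation
#'     subjects, 4 x 5 (634 subjects, two sides each).}
#'   \item{S34}{A1 developmental type x FTP formation, 4 x 2 (subject
#'     level).}
#' }
#' Known internal inconsistencies of the published tables are listed in the
#' packaged file `discrepancies.tsv` (see
#' `system.file("extdata", "discrepancies.tsv", package = "cowillis")`).
#'
#' @param id one of `"T1"`, `"T2"`, `"T3"`, `"T4"`, `"T5"`, `"T6"`, `"S34"`.
#' @return integer matrix of counts.
#' @examples
#' cow_printed_table("T2")
#' @export
cow_printed_table <- function(id = c("T1", "T2", "T3", "T4", "T5", "T6",
                                     "S34")) {
  id <- match.arg(id)
  file <- c(T1 = "table1.tsv", T2 = "table2.tsv", T3 = "table3.tsv",
            T4 = "table4.tsv", T5 = "table5.tsv", T6 = "table6.tsv",
            S34 = "table_s34.tsv")[[id]]
  path <- system.file("extdata", file, package = "cowillis", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
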