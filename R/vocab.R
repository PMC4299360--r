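#' Category vocabularies for circle-of-Willis typing
#'
#' Fixed, ordered label sets used throughout the package.  `cow_levels()`
#' returns the canonical level vector for one of the classification axes;
#' factors built by the classifier and aggregator always use these levels in
#' this order, so contingency tables keep a stable row/column layout even when
#' a cohort lacks some category.
#'
#' Axes:
#' \describe{
#'   \item{a1}{ACA-A1 developmental status, ordered by severity:
#'     `normal < mild_variation < hypoplasia < absent`.}
#'   \item{anterior}{Anterior-circulation types `I, II, III` (integral ring)
#'     and `IV, V1, V2` (nonintegral).}
#'   \item{pca}{Per-side posterior cerebral artery type: `adult`, the
#'     quasi-fetal subtypes `ftp_I`/`ftp_II` (P1 present), the pure fetal
#'     subtype `ftp_III` (P1 absent), and `ftp_IV` (dual PCA).}
#'   \item{posterior}{Posterior-circulation types `a`--`k`; `a`--`c` are
#'     integral, `d`--`k` nonintegral.}
#'   \item{cow}{Overall ring category: `integral`, `partial`, `nonintegral`.}
#'   \item{acoa_state}{Anterior communicating artery patency:
#'     `present`, `absent`, `unclear`.}
#'   \item{acoa_shape}{ACoA morphology; `none` iff the state is not
#'     `present`.}
#' }
#'
#' @param axis one of `"a1"`, `"anterior"`, `"pca"`, `"posterior"`, `"cow"`,
#'   `"acoa_state"`, `"acoa_shape"`.
#' @return character vector of level labels in canonical order.
#' @examples
#' cow_levels("anterior")
#' cow_levels("a1")
#' @export
cow_levels <- function(axis = c("a1", "anterior", "pca", "posterior", "cow",
                                "acoa_state", "acoa_shape")) {
  switch(match.arg(axis),
    a1         = c("normal", "mild_variation", "hypoplasia", "absent"),
    anterior   = c("I", "II", "III", "IV", "V1", "V2"),
    pca        = c("adult", "ftp_I", "ftp_II", "ftp_III", "ftp_IV"),
    posterior  = letters[1:11],
    cow        = c("integral", "partial", "nonintegral"),
    acoa_state = c("present", "absent", "unclear"),
    acoa_shape = c("single_tubular", "double_branch", "y_pattern",
                   "window_pattern", "ampulla", "circle_pattern", "none")
  )
}

#' Vessel-absence convention
#'
#' A vessel whose diameter is below 0.5 mm provides no effective collateral
#' perfusion and is treated as absent everywhere in the classifier, as is a
#' vessel that was not visualized at all (`NA`).
#'
#' @param d_mm numeric vector of diameters in millimetres; `NA` means the
#'   vessel was not visualized.
#' @return logical vector: `TRUE` where the vessel counts as absent.
#' @examples
#' vessel_absent(c(2.0, 0.4, NA))
#' @export
vessel_absent <- function(d_mm) {
  is.na(d_mm) | d_mm < COW_ABSENCE_MM
}

#' Diameter threshold (mm) below which a vessel is regarded as absent.
#' @export
COW_ABSENCE_MM <- 0.5

# anterior types whose half-ring is complete; posterior likewise
.integral_anterior <- c("I", "II", "III")
.integral_posterior <- c("a", "b", "c")

.as_level <- function(x, axis) {
  lev <- cow_levels(axis)
  f <- factor(as.character(x), levels = lev)
  if (anyNA(f) && !all(is.na(x) == is.na(f)))
    stop("invalid ", axis, " label(s): ",
         paste(unique(setdiff(as.character(x), lev)), collapse = ", "))
  f
}
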