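#' Cross-tabulate anterior by posterior type
#'
#' The 6 x 11 morphological-variation table of a classified cohort: cell
#' (x, y) counts subjects with anterior type x and posterior type y.  Rows
#' and columns follow the canonical level order, so absent categories appear
#' as zero rows/columns rather than disappearing.
#'
#' @param profiles a `cow_profiles` table from [classify_subjects()] or
#'   [reconstruct_from_crosstab()].
#' @return integer matrix with anterior types as rows, posterior types as
#'   columns.
#' @export
crosstab_cow <- function(profiles) {
  .as_counts(table(.as_level(profiles$anterior_type, "anterior"),
                   .as_level(profiles$posterior_type, "posterior")))
}

#' A1 balance versus anterior-ring integrity (2 x 2)
#'
#' Rows: balanced A1 development (types I, V1) versus unbalanced (II, III,
#' IV, V2).  Columns: integral anterior half-ring (I--III) versus
#' nonintegral (IV, V1, V2).
#'
#' @inheritParams crosstab_cow
#' @return 2 x 2 integer matrix.
#' @export
table_balance_integrity <- function(profiles) {
  ant <- .as_level(profiles$anterior_type, "anterior")
  balanced <- factor(ifelse(ant %in% c("I", "V1"), "balanced", "unbalanced"),
                     levels = c("balanced", "unbalanced"))
  integral <- factor(ifelse(ant %in% .integral_anterior, "integral",
                            "nonintegral"),
                     levels = c("integral", "nonintegral"))
  .as_counts(table(balanced, integral))
}

#' A1 developmental status by side (2 x 4)
#'
#' @inheritParams crosstab_cow
#' @return integer matrix with rows `L`, `R` and the four A1 status columns.
#' @export
table_a1_by_side <- function(profiles) {
  m <- rbind(L = table(.as_level(profiles$a1_status_left, "a1")),
             R = table(.as_level(profiles$a1_status_right, "a1")))
  .as_counts(m)
}

#' Normal versus variation lateral, by homolateral PCA type (4 x 5)
#'
#' Restricted to subjects with any A1 variation.  Each such subject
#' contributes two side-level observations: its normal lateral and its
#' variation lateral, each classified by that side's own A1 status (rows)
#' and that side's PCA type (columns).  When both sides show variation the
#' milder side stands in as the "normal lateral" row under its own status;
#' ties on severity take the left side as the normal lateral.
#'
#' @inheritParams crosstab_cow
#' @return 4 x 5 integer matrix (A1 status x PCA type); all-zero when the
#'   cohort has no A1 variation.
#' @export
table_a1var_sides_by_pca <- function(profiles) {
  sl <- as.integer(.as_level(profiles$a1_status_left, "a1"))
  sr <- as.integer(.as_level(profiles$a1_status_right, "a1"))
  var_sub <- sl > 1L | sr > 1L
  # variation lateral = the more severe side; left wins ties as the normal side
  var_is_right <- sr[var_sub] >= sl[var_sub]
  norm_status <- ifelse(var_is_right, sl[var_sub], sr[var_sub])
  var_status  <- ifelse(var_is_right, sr[var_sub], sl[var_sub])
  pl <- .as_level(profiles$pca_left, "pca")[var_sub]
  pr <- .as_level(profiles$pca_right, "pca")[var_sub]
  norm_pca <- ifelse(var_is_right, as.integer(pl), as.integer(pr))
  var_pca  <- ifelse(var_is_right, as.integer(pr), as.integer(pl))
  status <- factor(cow_levels("a1")[c(norm_status, var_status)],
                   levels = cow_levels("a1"))
  pca <- factor(cow_levels("pca")[c(norm_pca, var_pca)],
                levels = cow_levels("pca"))
  .as_counts(table(status, pca))
}

.as_counts <- function(tab) {
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Summarize a classified cohort
#'
#' Headline counts and proportions: ring-integrity categories, the
#' nonvariation-integral subgroup, anterior and posterior half-ring
#' integrity, subjects with any A1 variation, and subjects forming a
#' fetal-type PCA on either side.  Proportions are stored at full precision;
#' the print method shows them as percentages to two decimals.
#'
#' @inheritParams crosstab_cow
#' @return object of class `cow_summary`: a list with `n` and, for each
#'   quantity, `count` and `prop` entries.
#' @examples
#' profiles <- reconstruct_from_crosstab(cow_printed_table("T1"))
#' summarize_cohort(profiles)
#' @export
summarize_cohort <- function(profiles) {
  n <- nrow(profiles)
  stopifnot(n > 0)
  cat3 <- table(.as_level(profiles$cow_category, "cow"))
  ant <- .as_level(profiles$anterior_type, "anterior")
  pos <- .as_level(profiles$posterior_type, "posterior")
  nonvar <- sum(profiles$cow_category == "integral" &
                  !profiles$variation_flag, na.rm = TRUE)
  a1_var <- sum(profiles$a1_status_left != "normal" |
                  profiles$a1_status_right != "normal")
  ftp <- sum(profiles$pca_left != "adult" | profiles$pca_right != "adult")
  counts <- c(integral = unname(cat3["integral"]),
              partial = unname(cat3["partial"]),
              nonintegral = unname(cat3["nonintegral"]),
              nonvariation_integral = nonvar,
              anterior_integral = sum(ant %in% .integral_anterior),
              posterior_integral = sum(pos %in% .integral_posterior),
              posterior_nonintegral = sum(!pos %in% .integral_posterior),
              a1_variation = a1_var,
              ftp_forming = ftp)
  structure(list(n = n, counts = counts, props = counts / n),
            class = "cow_summary")
}

#' @export
print.cow_summary <- function(x, ...) {
  cat("Circle-of-Willis cohort summary (n =", x$n, "subjects)\n\n")
  lab <- c(integral = "Integral COW", partial = "Partially integral COW",
           nonintegral = "Nonintegral COW",
           nonvariation_integral = "  of integral: nonvariation",
           anterior_integral = "Integral anterior circulation",
           posterior_integral = "Integral posterior circulation",
           posterior_nonintegral = "Nonintegral posterior circulation",
           a1_variation = "Subjects with ACA-A1 variation",
           ftp_forming = "Subjects forming fetal-type PCA")
  for (k in names(x$counts))
    cat(sprintf("  %-35s %5d  (%6.2f%%)\n", lab[[k]], x$counts[[k]],
                100 * x$props[[k]]))
  invisible(x)
}

#' @export
print.cow_profiles <- function(x, ...) {
  cat("Classified circle-of-Willis profiles:", nrow(x), "subjects\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.cow_profiles <- function(object, ...) summarize_cohort(object)
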