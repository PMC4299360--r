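#' Build a subject vessel-measurement table
#'
#' Constructs (and checks the shape of) the canonical per-subject measurement
#' table used by the classifier.  One row per subject; diameters are in
#' millimetres with `NA` meaning the vessel was not visualized, which is
#' deliberately distinct from any numeric diameter.
#'
#' Required columns (the subject CSV dialect):
#' `subject_id`, `a1_left_mm`, `a1_right_mm`, `acoa_state`, `acoa_shape`,
#' `pcoa_left_mm`, `pcoa_right_mm`, `p1_left_mm`, `p1_right_mm`,
#' `dual_pca_left`, `dual_pca_right`, `trigeminal_variant`.
#' Unknown columns are preserved and ignored.
#'
#' @param data data.frame containing at least the required columns.
#' @return the same data.frame, with diameters numeric, flags logical, and
#'   class `cow_records` prepended.
#' @seealso [validate_records()], [read_subjects()]
#' @export
cow_records <- function(data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(cow_record_columns(), names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in .diameter_cols) data[[col]] <- as.numeric(data[[col]])
  for (col in .flag_cols) data[[col]] <- .as_flag(data[[col]], col)
  data$subject_id <- as.character(data$subject_id)
  data$acoa_state <- as.character(data$acoa_state)
  data$acoa_shape <- as.character(data$acoa_shape)
  class(data) <- c("cow_records", class(data))
  data
}

#' @rdname cow_records
#' @export
cow_record_columns <- function() {
  c("subject_id", .diameter_cols[1:2], "acoa_state", "acoa_shape",
    .diameter_cols[3:6], .flag_cols)
}

.diameter_cols <- c("a1_left_mm", "a1_right_mm", "pcoa_left_mm",
                    "pcoa_right_mm", "p1_left_mm", "p1_right_mm")
.flag_cols <- c("dual_pca_left", "dual_pca_right", "trigeminal_variant")

.as_flag <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.character(x) && all(toupper(x) %in% c("TRUE", "FALSE", NA)))
    return(as.logical(toupper(x)))
  v <- suppressWarnings(as.integer(x))
  bad <- !is.na(v) & !v %in% c(0L, 1L)
  if (any(bad) || (anyNA(v) & !anyNA(x)))
    stop("column ", col, " must be 0/1 or logical")
  as.logical(v)
}

#' Validate one subject record
#'
#' Checks every data-model invariant and returns the violations as data, not
#' as a condition: an empty character vector means the record is well formed.
#' Each violation names the offending field.  A diameter of exactly 0.0 is
#' rejected as ambiguous: sub-threshold vessels are recorded as absent
#' (`NA`), never as zero-width.
#'
#' @param record a one-row data.frame (or list) with the columns of
#'   [cow_records()].
#' @return character vector of violation messages (empty if valid).
#' @examples
#' rec <- data.frame(subject_id = "s1", a1_left_mm = 2, a1_right_mm = 2,
#'   acoa_state = "present", acoa_shape = "single_tubular",
#'   pcoa_left_mm = 1.2, pcoa_right_mm = 1.2, p1_left_mm = 2, p1_right_mm = 2,
#'   dual_pca_left = FALSE, dual_pca_right = FALSE, trigeminal_variant = FALSE)
#' validate_record(rec)  # character(0)
#' @export
validate_record <- function(record) {
  v <- character(0)
  for (col in .diameter_cols) {
    d <- record[[col]]
    if (is.null(d)) { v <- c(v, paste0(col, ": missing field")); next }
    d <- suppressWarnings(as.numeric(d))
    if (!is.na(d) && d < 0)
      v <- c(v, paste0(col, ": negative diameter (", d, " mm)"))
    else if (!is.na(d) && d == 0)
      v <- c(v, paste0(col, ": zero diameter is ambiguous; use NA for a ",
                       "vessel regarded as absent"))
  }
  st <- as.character(record[["acoa_state"]])
  sh <- as.character(record[["acoa_shape"]])
  if (!st %in% cow_levels("acoa_state"))
    v <- c(v, paste0("acoa_state: unknown value '", st, "'"))
  if (!sh %in% cow_levels("acoa_shape"))
    v <- c(v, paste0("acoa_shape: unknown value '", sh, "'"))
  else if (st %in% cow_levels("acoa_state")) {
    if (st == "present" && sh == "none")
      v <- c(v, "acoa_shape: must not be 'none' when acoa_state is 'present'")
    if (st != "present" && sh != "none")
      v <- c(v, paste0("acoa_shape: must be 'none' when acoa_state is '",
                       st, "'"))
  }
  for (col in .flag_cols) {
    f <- record[[col]]
    if (is.null(f) || is.na(f) || !(is.logical(f) || f %in% c(0, 1)))
      v <- c(v, paste0(col, ": must be a 0/1 flag"))
  }
  v
}

#' Validate a whole measurement table
#'
#' @param records a [cow_records()] table.
#' @return data.frame with columns `row`, `subject_id`, `violation`; zero rows
#'   when every record is valid.
#' @export
validate_records <- function(records) {
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    vi <- validate_record(records[i, , drop = FALSE])
    if (length(vi))
      out[[i]] <- data.frame(row = i, subject_id = records$subject_id[i],
                             violation = vi, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(row = integer(0), subject_id = character(0),
                      violation = character(0)))
  do.call(rbind, out)
}
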