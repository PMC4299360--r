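#' Classify ACA-A1 developmental status, per side
#'
#' Grades each A1 segment against its contralateral partner, choosing the
#' most severe satisfied class:
#' \itemize{
#'   \item \strong{absent} — not visualized, or diameter < 0.5 mm;
#'   \item \strong{hypoplasia} — diameter less than half the contralateral
#'     diameter, or the smaller side of a pair differing by more than 1.0 mm;
#'   \item \strong{mild_variation} — the smaller side when the left/right
#'     difference lies in [0.5, 1.0] mm (both bounds inclusive);
#'   \item \strong{normal} — otherwise.  The larger side of an asymmetric
#'     pair is normal unless itself below 0.5 mm; when the contralateral
#'     vessel is absent the surviving side is graded normal.
#' }
#'
#' @param a1_left,a1_right numeric diameters in mm (`NA` = not visualized).
#'   Vectorized over subjects.
#' @return data.frame with factor columns `left`, `right` over
#'   `cow_levels("a1")`.
#' @examples
#' classify_a1(2.2, 1.5)  # 0.7 mm difference: right side mild_variation
#' classify_a1(2.2, 1.0)  # 1.0 < 2.2 / 2: right side hypoplasia
#' @export
classify_a1 <- function(a1_left, a1_right) {
  data.frame(left  = .a1_side(a1_left, a1_right),
             right = .a1_side(a1_right, a1_left))
}

.a1_side <- function(d, contra) {
  out <- rep("normal", length(d))
  diff <- contra - d                       # positive when this is the smaller side
  hypo <- !vessel_absent(d) & !vessel_absent(contra) &
    (d < contra / 2 | diff > 1.0)
  mild <- !vessel_absent(d) & !vessel_absent(contra) & diff >= 0.5 & diff <= 1.0
  out[mild] <- "mild_variation"
  out[hypo] <- "hypoplasia"                # severity precedence over mild
  out[vessel_absent(d)] <- "absent"
  factor(out, levels = cow_levels("a1"))
}

#' Classify the anterior circulation type
#'
#' Combines the two A1 grades with ACoA patency into types I--V2.  A1
#' absence decides type IV regardless of the ACoA; an `unclear` ACoA is
#' treated as not patent, so balanced/unbalanced development maps to V1/V2.
#'
#' @param a1_status data.frame as returned by [classify_a1()] (columns
#'   `left`, `right`), or a length-2 vector of A1 labels for one subject.
#' @param acoa_state character vector over `cow_levels("acoa_state")`.
#' @return factor over `cow_levels("anterior")`.
#' @examples
#' classify_anterior(classify_a1(2.0, 2.0), "present")  # type I
#' classify_anterior(classify_a1(2.0, 2.0), "absent")   # type V1
#' @export
classify_anterior <- function(a1_status, acoa_state) {
  if (!is.data.frame(a1_status))
    a1_status <- data.frame(left = .as_level(a1_status[1], "a1"),
                            right = .as_level(a1_status[2], "a1"))
  l <- as.integer(.as_level(a1_status$left, "a1"))
  r <- as.integer(.as_level(a1_status$right, "a1"))
  worst <- pmax(l, r)                      # severity order of the levels
  patent <- acoa_state == "present"
  out <- character(length(worst))
  out[worst == 4L] <- "IV"
  out[worst < 4L & patent]  <- c("I", "II", "III")[worst[worst < 4L & patent]]
  out[worst == 1L & !patent] <- "V1"
  out[worst %in% 2:3 & !patent] <- "V2"
  factor(out, levels = cow_levels("anterior"))
}

#' Classify one posterior cerebral artery side
#'
#' Adult type means the P1 segment carries the PCA (its diameter is at least
#' that of the ipsilateral PCoA).  The fetal-type (FTP) subtypes are:
#' `ftp_I` — P1 present but narrower than the ipsilateral PCoA;
#' `ftp_II` — P1 present, below half the contralateral P1, and narrower than
#' the PCoA; `ftp_III` — pure fetal type, P1 absent and the PCA formed by
#' PCoA extension; `ftp_IV` — dual PCA fed by both the basilar and the
#' internal carotid artery.  Equality of P1 and PCoA diameters is adult
#' (fetal type requires strictly smaller P1).
#'
#' @param p1 numeric P1 diameter on this side (mm, `NA` = not visualized).
#' @param p1_contra contralateral P1 diameter.
#' @param pcoa ipsilateral PCoA diameter.
#' @param dual_pca logical dual-PCA flag for this side.
#' @return factor over `cow_levels("pca")`.
#' @examples
#' classify_pca_side(2.0, 2.0, 1.2, FALSE)  # adult
#' classify_pca_side(1.4, 1.5, 1.6, FALSE)  # ftp_I
#' classify_pca_side(NA, 2.0, 1.8, FALSE)   # ftp_III (pure fetal type)
#' @export
classify_pca_side <- function(p1, p1_contra, pcoa, dual_pca) {
  n <- max(length(p1), length(dual_pca))
  p1 <- rep_len(p1, n); p1_contra <- rep_len(p1_contra, n)
  pcoa <- rep_len(pcoa, n); dual_pca <- rep_len(dual_pca, n)
  p1_abs <- vessel_absent(p1); pcoa_abs <- vessel_absent(pcoa)
  dead <- p1_abs & pcoa_abs & !dual_pca
  if (any(dead))
    stop("no posterior supply on side: P1 and PCoA both absent (record ",
         paste(which(dead), collapse = ", "), ")")
  out <- rep("adult", n)
  lt_pcoa <- !p1_abs & !pcoa_abs & p1 < pcoa
  out[lt_pcoa] <- "ftp_I"
  out[lt_pcoa & !vessel_absent(p1_contra) & p1 < p1_contra / 2] <- "ftp_II"
  out[p1_abs] <- "ftp_III"
  out[dual_pca] <- "ftp_IV"
  factor(out, levels = cow_levels("pca"))
}

#' Classify the posterior circulation type
#'
#' Maps the pair of per-side PCA types together with PCoA presence
#' (diameter >= 0.5 mm) to types `a`--`k`.  Writing Q for a quasi-fetal side
#' (`ftp_I`/`ftp_II`) and P for a pure fetal side (`ftp_III`):
#' `a` both PCoA present, both adult; `b` both present, both Q; `c` both
#' present, one Q one adult; `d` both PCoA absent, both adult; `e` one PCoA
#' present, both adult; `f` one PCoA present and that side Q; `g` one PCoA
#' present and that side P; `h` both present, one P one adult; `i` both
#' present, one P one Q; `j` both sides P; `k` any dual PCA (`ftp_IV`).
#' Combinations outside this list (e.g. a fetal-type side whose own PCoA is
#' absent) are rejected as unclassifiable.
#'
#' @param pca data.frame with factor columns `left`, `right` over
#'   `cow_levels("pca")`, or a length-2 label vector for one subject.
#' @param pcoa_left,pcoa_right numeric PCoA diameters (mm, `NA` absent).
#' @return factor over `cow_levels("posterior")`.
#' @examples
#' classify_posterior(c("adult", "adult"), NA, NA)   # type d
#' classify_posterior(c("ftp_III", "ftp_III"), 1.6, 1.6)  # type j
#' @export
classify_posterior <- function(pca, pcoa_left, pcoa_right) {
  if (!is.data.frame(pca))
    pca <- data.frame(left = .as_level(pca[1], "pca"),
                      right = .as_level(pca[2], "pca"))
  tl <- as.character(.as_level(pca$left, "pca"))
  tr <- as.character(.as_level(pca$right, "pca"))
  n <- length(tl)
  pl <- !vessel_absent(rep_len(pcoa_left, n))
  pr <- !vessel_absent(rep_len(pcoa_right, n))
  grp <- function(x) ifelse(x == "adult", "A",
                     ifelse(x %in% c("ftp_I", "ftp_II"), "Q",
                     ifelse(x == "ftp_III", "P", "K")))
  gl <- grp(tl); gr <- grp(tr)
  out <- rep(NA_character_, n)
  both <- pl & pr; none <- !pl & !pr; one <- xor(pl, pr)
  out[both & gl == "A" & gr == "A"] <- "a"
  out[both & gl == "Q" & gr == "Q"] <- "b"
  out[both & ((gl == "Q" & gr == "A") | (gl == "A" & gr == "Q"))] <- "c"
  out[none & gl == "A" & gr == "A"] <- "d"
  out[one & gl == "A" & gr == "A"] <- "e"
  side <- ifelse(pl, gl, gr)               # type of the PCoA-bearing side
  opp  <- ifelse(pl, gr, gl)
  out[one & side == "Q" & opp == "A"] <- "f"
  out[one & side == "P" & opp == "A"] <- "g"
  out[both & ((gl == "P" & gr == "A") | (gl == "A" & gr == "P"))] <- "h"
  out[both & ((gl == "P" & gr == "Q") | (gl == "Q" & gr == "P"))] <- "i"
  out[both & gl == "P" & gr == "P"] <- "j"
  out[gl == "K" | gr == "K"] <- "k"
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop("unclassifiable posterior pattern (record ", i, "): left ", tl[i],
         if (pl[i]) " with" else " without", " PCoA, right ", tr[i],
         if (pr[i]) " with" else " without", " PCoA")
  }
  factor(out, levels = cow_levels("posterior"))
}

#' Classify overall circle-of-Willis integrity
#'
#' The ring is `integral` when both half-rings are complete (anterior I--III
#' and posterior a--c), `nonintegral` when neither is, and `partial`
#' otherwise.  For integral rings a developmental-variation flag marks
#' hypoplasia anywhere on the ring: anterior type III, or posterior type
#' b/c.  The flag is `NA` for non-integral categories.
#'
#' @param anterior,posterior factors (or labels) over the anterior/posterior
#'   vocabularies.
#' @return data.frame with columns `cow_category` (factor over
#'   `cow_levels("cow")`) and `variation_flag` (logical).
#' @examples
#' classify_cow("I", "a")    # integral, no variation
#' classify_cow("III", "a")  # integral, variation flagged
#' classify_cow("I", "d")    # partial
#' @export
classify_cow <- function(anterior, posterior) {
  ant <- .as_level(anterior, "anterior")
  pos <- .as_level(posterior, "posterior")
  ant_int <- ant %in% .integral_anterior
  pos_int <- pos %in% .integral_posterior
  cat <- ifelse(ant_int & pos_int, "integral",
         ifelse(!ant_int & !pos_int, "nonintegral", "partial"))
  flag <- ifelse(cat == "integral", ant == "III" | pos %in% c("b", "c"), NA)
  data.frame(cow_category = factor(cat, levels = cow_levels("cow")),
             variation_flag = flag)
}

#' Classify a cohort of subject records
#'
#' Runs the full typing pipeline — A1 grading, anterior type, per-side PCA
#' type, posterior type, and ring integrity — over a measurement table.
#' Purely deterministic: re-classifying the same records reproduces the same
#' profiles.
#'
#' @param records a [cow_records()] table (it is validated first; invalid
#'   rows raise an error listing them).
#' @return data.frame of class `cow_profiles` with columns `subject_id`,
#'   `a1_status_left`, `a1_status_right`, `anterior_type`, `pca_left`,
#'   `pca_right`, `posterior_type`, `cow_category`, `variation_flag`.
#' @examples
#' rec <- sample_cohort(cohort_spec(n = 5, seed = 1))
#' classify_subjects(rec)
#' @export
classify_subjects <- function(records) {
  if (!inherits(records, "cow_records")) records <- cow_records(records)
  bad <- validate_records(records)
  if (nrow(bad))
    stop("invalid record(s):\n",
         paste(sprintf("  row %d (%s): %s", bad$row, bad$subject_id,
                       bad$violation)[seq_len(min(10, nrow(bad)))],
               collapse = "\n"))
  a1 <- classify_a1(records$a1_left_mm, records$a1_right_mm)
  ant <- classify_anterior(a1, records$acoa_state)
  pca <- data.frame(
    left = classify_pca_side(records$p1_left_mm, records$p1_right_mm,
                             records$pcoa_left_mm, records$dual_pca_left),
    right = classify_pca_side(records$p1_right_mm, records$p1_left_mm,
                              records$pcoa_right_mm, records$dual_pca_right))
  pos <- classify_posterior(pca, records$pcoa_left_mm, records$pcoa_right_mm)
  cw <- classify_cow(ant, pos)
  out <- data.frame(subject_id = records$subject_id,
                    a1_status_left = a1$left, a1_status_right = a1$right,
                    anterior_type = ant,
                    pca_left = pca$left, pca_right = pca$right,
                    posterior_type = pos,
                    cow_category = cw$cow_category,
                    variation_flag = cw$variation_flag)
  class(out) <- c("cow_profiles", class(out))
  out
}

#' @rdname classify_subjects
#' @param record a single one-row record.
#' @export
classify_subject <- function(record) {
  classify_subjects(record[1, , drop = FALSE])
}
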