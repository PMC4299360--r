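# interleaved (left, right) status labels per subject pair
a1 <- function(l, r) {
  s <- classify_a1(l, r)
  as.vector(t(cbind(as.character(s$left), as.character(s$right))))
}

test_that("A1 grading follows the side-difference rules", {
  expect_equal(a1(2.0, 2.0), c("normal", "normal"))
  expect_equal(a1(2.2, 1.5), c("normal", "mild_variation"))  # diff 0.7
  expect_equal(a1(2.2, 1.0), c("normal", "hypoplasia"))      # 1.0 < 2.2/2
  expect_equal(a1(2.0, NA), c("normal", "absent"))
  expect_equal(a1(NA, NA), c("absent", "absent"))
  expect_equal(a1(0.4, 2.0), c("absent", "normal"))          # < 0.5 mm
})

test_that("A1 boundary conventions: inclusive mild band, severity wins", {
  expect_equal(a1(2.0, 1.5)[2], "mild_variation")   # diff exactly 0.5
  expect_equal(a1(2.5, 1.5)[2], "mild_variation")   # diff exactly 1.0
  expect_equal(a1(2.0, 1.51)[2], "normal")          # diff below 0.5
  # satisfies both the mild band and the half-contralateral rule
  expect_equal(a1(1.8, 0.85)[2], "hypoplasia")
  # difference > 1.0 mm with smaller side >= half contralateral
  expect_equal(a1(3.0, 1.7)[2], "hypoplasia")
  # the larger side of an asymmetric pair stays normal
  expect_equal(a1(3.0, 1.7)[1], "normal")
})

test_that("A1 severity is monotone as one side shrinks", {
  d <- seq(2.2, 0.05, by = -0.05)
  status <- classify_a1(rep(2.2, length(d)), d)$right
  expect_true(all(diff(as.integer(status)) >= 0))
  expect_equal(a1(rep(2.2, 3), c(1.5, 1.0, 0.4))[c(2, 4, 6)],
               c("mild_variation", "hypoplasia", "absent"))
})

test_that("anterior typing combines A1 grades with ACoA patency", {
  ant <- function(l, r, st)
    as.character(classify_anterior(classify_a1(l, r), st))
  expect_equal(ant(2.0, 2.0, "present"), "I")
  expect_equal(ant(2.0, 2.0, "absent"), "V1")
  expect_equal(ant(2.0, NA, "present"), "IV")
  expect_equal(ant(2.2, 1.0, "absent"), "V2")
  expect_equal(ant(2.2, 1.5, "present"), "II")
  expect_equal(ant(2.2, 1.0, "present"), "III")
  # A1 absence decides IV regardless of the ACoA
  expect_equal(ant(2.0, NA, "absent"), "IV")
  # unclear ACoA folds into "not patent" for typing
  expect_equal(ant(2.0, 2.0, "unclear"), "V1")
  expect_equal(ant(2.2, 1.5, "unclear"), "V2")
})

test_that("per-side PCA typing distinguishes adult and fetal subtypes", {
  pca <- function(...) as.character(classify_pca_side(...))
  expect_equal(pca(2.0, 2.0, 1.2, FALSE), "adult")
  expect_equal(pca(1.4, 1.5, 1.6, FALSE), "ftp_I")
  expect_equal(pca(0.8, 2.0, 1.6, FALSE), "ftp_II")
  expect_equal(pca(NA, 2.0, 1.8, FALSE), "ftp_III")
  expect_equal(pca(2.0, 2.0, 1.2, TRUE), "ftp_IV")
  # equality with the PCoA is adult: fetal type needs strictly smaller P1
  expect_equal(pca(1.5, 1.5, 1.5, FALSE), "adult")
  # PCoA absent with a present P1 is adult
  expect_equal(pca(2.0, 2.0, NA, FALSE), "adult")
  expect_error(classify_pca_side(NA, 2.0, NA, FALSE), "no posterior supply")
})

test_that("posterior typing maps side patterns to types a-k", {
  post <- function(pca, l, r) as.character(classify_posterior(pca, l, r))
  expect_equal(post(c("adult", "adult"), 1.2, 1.2), "a")
  expect_equal(post(c("ftp_I", "ftp_II"), 1.6, 1.6), "b")
  expect_equal(post(c("ftp_I", "adult"), 1.6, 1.2), "c")
  expect_equal(post(c("adult", "adult"), NA, NA), "d")
  expect_equal(post(c("adult", "adult"), 1.2, NA), "e")
  expect_equal(post(c("ftp_I", "adult"), 1.6, NA), "f")
  expect_equal(post(c("ftp_III", "adult"), 1.6, NA), "g")
  expect_equal(post(c("ftp_III", "adult"), 1.6, 1.2), "h")
  expect_equal(post(c("ftp_III", "ftp_I"), 1.6, 1.6), "i")
  expect_equal(post(c("ftp_III", "ftp_III"), 1.6, 1.6), "j")
  expect_equal(post(c("ftp_IV", "adult"), 1.2, 1.2), "k")
  # a fetal-type side whose own PCoA is absent is unclassifiable
  expect_error(classify_posterior(c("ftp_I", "adult"), NA, 1.2),
               "unclassifiable")
})

test_that("ring categorization partitions and flags hypoplastic variation", {
  cw <- classify_cow(c("I", "I", "V1", "III"), c("a", "d", "e", "a"))
  expect_equal(as.character(cw$cow_category),
               c("integral", "partial", "nonintegral", "integral"))
  expect_equal(cw$variation_flag, c(FALSE, NA, NA, TRUE))
  # posterior quasi/pure fetal columns flag variation too
  expect_true(classify_cow("I", "b")$variation_flag)
  expect_true(classify_cow("II", "c")$variation_flag)
  expect_false(classify_cow("II", "a")$variation_flag)
})

test_that("variation flag audits to 105 of 275 integral on the printed cohort", {
  prof <- reconstruct_from_crosstab(cow_printed_table("T1"))
  expect_equal(sum(prof$variation_flag, na.rm = TRUE), 105)
  expect_equal(sum(!is.na(prof$variation_flag)), 275)
})

test_that("classify_subject composes the component rules", {
  p <- classify_subject(make_record())
  expect_equal(as.character(p$anterior_type), "I")
  expect_equal(as.character(p$posterior_type), "a")
  expect_equal(as.character(p$cow_category), "integral")
  expect_false(p$variation_flag)

  p2 <- classify_subject(make_record(a1_right_mm = NA,
                                     pcoa_left_mm = NA, pcoa_right_mm = NA))
  expect_equal(as.character(p2$anterior_type), "IV")
  expect_equal(as.character(p2$posterior_type), "d")
  expect_equal(as.character(p2$cow_category), "nonintegral")

  p3 <- classify_subject(make_record(dual_pca_left = TRUE))
  expect_equal(as.character(p3$posterior_type), "k")

  expect_error(classify_subjects(make_record(a1_left_mm = -1)), "invalid")
})

test_that("classification is exhaustive and exclusive on sampled cohorts", {
  u <- function(axis) {
    lev <- cow_levels(axis)
    stats::setNames(rep(1 / length(lev), length(lev)), lev)
  }
  rec <- sample_cohort(cohort_spec(n = 300, anterior_probs = u("anterior"),
                                   posterior_probs = u("posterior"),
                                   seed = 11))
  prof <- classify_subjects(rec)
  expect_false(anyNA(prof$anterior_type))
  expect_false(anyNA(prof$posterior_type))
  expect_false(anyNA(prof$cow_category))
  # category arithmetic: the three ring categories partition the cohort
  expect_equal(sum(table(prof$cow_category)), nrow(prof))
})
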