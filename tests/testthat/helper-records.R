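# Build a well-formed subject record, overriding any field by name.
make_record <- function(...) {
  rec <- data.frame(
    subject_id = "s1",
    a1_left_mm = 2.0, a1_right_mm = 2.0,
    acoa_state = "present", acoa_shape = "single_tubular",
    pcoa_left_mm = 1.2, pcoa_right_mm = 1.2,
    p1_left_mm = 2.0, p1_right_mm = 2.0,
    dual_pca_left = FALSE, dual_pca_right = FALSE,
    trigeminal_variant = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# A minimal hand-built profiles table (bypasses the classifier) for
# aggregation tests.
make_profiles <- function(anterior, posterior,
                          a1_left = "normal", a1_right = "normal",
                          pca_left = "adult", pca_right = "adult") {
  n <- max(length(anterior), length(posterior))
  cw <- classify_cow(rep_len(anterior, n), rep_len(posterior, n))
  out <- data.frame(
    subject_id = sprintf("p%03d", seq_len(n)),
    a1_status_left = factor(rep_len(a1_left, n), cow_levels("a1")),
    a1_status_right = factor(rep_len(a1_right, n), cow_levels("a1")),
    anterior_type = factor(rep_len(anterior, n), cow_levels("anterior")),
    pca_left = factor(rep_len(pca_left, n), cow_levels("pca")),
    pca_right = factor(rep_len(pca_right, n), cow_levels("pca")),
    posterior_type = factor(rep_len(posterior, n), cow_levels("posterior")),
    cow_category = cw$cow_category,
    variation_flag = cw$variation_flag)
  class(out) <- c("cow_profiles", class(out))
  out
}

# Random non-degenerate count table for statistical property tests.
random_table <- function(nr, nc, lambda = 20) {
  repeat {
    m <- matrix(stats::rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
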