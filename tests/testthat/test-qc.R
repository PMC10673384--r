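toy_matrix <- function(abund, individuals = NULL) {
  n <- nrow(abund)
  if (is.null(colnames(abund)))
    colnames(abund) <- sprintf("m%02d", seq_len(ncol(abund)))
  rownames(abund) <- sprintf("s%02d", seq_len(n))
  if (is.null(individuals)) individuals <- rownames(abund)
  metab_matrix(abund, data.frame(sample_id = rownames(abund),
                                 individual_id = individuals,
                                 age = 50 + seq_len(n), fluid = "plasma"))
}

test_that("metabolite missingness filter is strictly greater-than", {
  ab <- matrix(runif(30, 1, 10), 10, 3)
  ab[1:6, 1] <- NA    # 0.6 missing: removed
  ab[1:5, 2] <- NA    # exactly 0.5: retained
  x <- toy_matrix(ab)
  res <- filter_metabolites_by_missingness(x, 0.5)
  expect_identical(res$removed, "m01")
  expect_identical(colnames(res$matrix$abund), c("m02", "m03"))

  # no missing values: identity
  clean <- toy_matrix(matrix(runif(30, 1, 10), 10, 3))
  res2 <- filter_metabolites_by_missingness(clean, 0.5)
  expect_identical(res2$matrix$abund, clean$abund)
  expect_length(res2$removed, 0)
})

test_that("sample missingness filter removes rows above 40%", {
  ab <- matrix(runif(100, 1, 10), 10, 10)
  ab[1, 1:5] <- NA    # 50% > 40%: removed
  ab[2, 1:4] <- NA    # exactly 40%: retained
  x <- toy_matrix(ab)
  res <- filter_samples_by_missingness(x, 0.4)
  expect_identical(res$removed, "s01")
  expect_equal(nrow(res$matrix$abund), 9)
  expect_identical(res$matrix$meta$sample_id, sprintf("s%02d", 2:10))
})

test_that("filters agree with brute-force counting on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    ab <- matrix(runif(12 * 8, 1, 10), 12, 8,
                 dimnames = list(sprintf("s%02d", 1:12),
                                 sprintf("m%02d", 1:8)))
    ab[sample(length(ab), 30)] <- NA
    x <- toy_matrix(ab)
    # column-wise brute force
    rm_m <- colnames(ab)[sapply(seq_len(ncol(ab)), function(j)
      sum(is.na(ab[, j])) / nrow(ab) > 0.3)]
    expect_identical(filter_metabolites_by_missingness(x, 0.3)$removed, rm_m)
    # row-wise brute force
    rm_s <- rownames(x$abund)[sapply(seq_len(nrow(ab)), function(i)
      sum(is.na(ab[i, ])) / ncol(ab) > 0.3)]
    expect_identical(filter_samples_by_missingness(x, 0.3)$removed, rm_s)
  }
})

test_that("zero-IQR filter uses the interpolated quantile rule", {
  ab <- cbind(const = rep(3, 4),
              near = c(1, 1, 1, 2),
              rising = c(1, 2, 3, 4))
  x <- toy_matrix(ab)
  res <- filter_zero_iqr(x)
  # hand computation for c(1,1,1,2), type-7: q25 = 1, q75 = 1.25, IQR 0.25 > 0
  expect_identical(res$removed, "const")
  expect_identical(colnames(res$matrix$abund), c("near", "rising"))

  # fewer than two observed values: degenerate, removed and logged
  ab2 <- cbind(solo = c(5, NA, NA, NA), ok = c(1, 2, 3, 4))
  res2 <- filter_zero_iqr(toy_matrix(ab2))
  expect_identical(res2$removed, "solo")
  expect_identical(res2$degenerate, "solo")
})

test_that("log10 transform maps observed entries and keeps missing", {
  ab <- cbind(a = c(100, 1, NA), b = c(10, 1000, 0.1))
  x <- toy_matrix(ab)
  out <- log10_transform(x)
  expect_equal(out$abund[, "a"], c(s01 = 2, s02 = 0, s03 = NA))
  expect_equal(out$abund[, "b"], c(s01 = 1, s02 = 3, s03 = -1))

  # round trip
  set.seed(4)
  v <- runif(20, -3, 3)
  x2 <- toy_matrix(matrix(10^v, 5, 4))
  expect_equal(as.numeric(log10_transform(x2)$abund), v, tolerance = 1e-12)

  # non-positive entries are an error naming metabolite and sample
  bad <- toy_matrix(cbind(a = c(1, -2, 3)))
  expect_error(log10_transform(bad), "'a'.*'s02'")
})

test_that("QC cascade accounting identities hold and order is fixed", {
  # zero-IQR status changes when the high-missingness sample is dropped:
  # metabolite 'tricky' is constant except in sample s01, and s01 is
  # removed by the sample filter, so 'tricky' is removed only because
  # the IQR filter runs after sample removal
  ab <- matrix(runif(60, 1, 10), 6, 10)
  colnames(ab) <- c("tricky", sprintf("m%02d", 2:10))
  ab[, "tricky"] <- c(9, rep(2, 5))
  ab[1, 2:6] <- NA                       # s01: 5/10 missing > 0.4
  x <- toy_matrix(ab)
  res <- run_qc(x, qc_config())
  r <- res$report
  expect_identical(r$removed_ids$samples, "s01")
  expect_identical(r$removed_ids$zero_iqr, "tricky")
  expect_equal(r$final_metabolites,
               r$initial_metabolites - r$removed_missing_metabolites -
                 r$removed_zero_iqr_metabolites)
  expect_equal(r$final_samples, r$initial_samples - r$removed_samples)

  # clean matrix: no removals, and the filters are idempotent on the result
  clean <- toy_matrix(matrix(runif(40, 1, 10), 8, 5))
  res2 <- run_qc(clean, qc_config())
  expect_equal(res2$report$removed_missing_metabolites, 0)
  expect_equal(res2$report$removed_samples, 0)
  expect_equal(res2$report$removed_zero_iqr_metabolites, 0)
  again <- res2$matrix
  expect_length(filter_metabolites_by_missingness(again, 0.5)$removed, 0)
  expect_length(filter_samples_by_missingness(again, 0.4)$removed, 0)
  expect_length(filter_zero_iqr(again)$removed, 0)
})

test_that("cascade results match an independent re-implementation", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    ab <- matrix(10^runif(15 * 12, 0, 3), 15, 12,
                 dimnames = list(sprintf("s%02d", 1:15),
                                 sprintf("m%02d", 1:12)))
    ab[sample(length(ab), 60)] <- NA
    ab[, 2] <- 7                                      # constant column
    x <- toy_matrix(ab)
    res <- run_qc(x, qc_config())
    # brute force: same three filters written longhand
    keep_m <- colMeans(is.na(ab)) <= 0.5
    ab2 <- ab[, keep_m, drop = FALSE]
    keep_s <- rowMeans(is.na(ab2)) <= 0.4
    ab3 <- ab2[keep_s, , drop = FALSE]
    iqr_ok <- apply(ab3, 2, function(v) {
      v <- v[!is.na(v)]
      length(v) >= 2 && (quantile(v, 0.75) - quantile(v, 0.25)) > 0
    })
    expect_equal(res$report$final_metabolites, sum(iqr_ok))
    expect_equal(res$report$final_samples, sum(keep_s))
    expect_equal(res$matrix$abund,
                 log10(ab3[, iqr_ok, drop = FALSE]))
  }
})

test_that("missingness removal is monotone in the threshold", {
  set.seed(77)
  ab <- matrix(runif(200, 1, 10), 20, 10)
  ab[sample(length(ab), 90)] <- NA
  x <- toy_matrix(ab)
  prev <- character(0)
  for (thr in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    rem <- filter_metabolites_by_missingness(x, thr)$removed
    expect_true(all(prev %in% rem))
    prev <- rem
  }
})

test_that("half-minimum imputation mode fills residual missingness", {
  ab <- cbind(a = c(2, 4, NA, 8), b = c(1, 10, 100, 1000),
              c = c(5, 6, 7, 8), d = c(2, 3, 4, 5))
  x <- toy_matrix(ab)
  res <- run_qc(x, qc_config(impute_half_min = TRUE))
  expect_false(any(is.na(res$matrix$abund)))
  expect_equal(res$matrix$abund["s03", "a"], log10(1))  # half of min 2
})

test_that("samples map to the age-nearest visit, ties to earlier", {
  samples <- data.frame(sample_id = c("a", "b"),
                        individual_id = c("I1", "I1"),
                        age = c(60, 60))
  visits1 <- data.frame(individual_id = c("I1", "I1"),
                        visit = c(2, 3), age = c(58, 61))
  expect_equal(match_samples_to_visits(samples[1, ], visits1)$visit, 3)
  visits2 <- data.frame(individual_id = c("I1", "I1"),
                        visit = c(2, 3), age = c(59, 61))
  expect_equal(match_samples_to_visits(samples[1, ], visits2)$visit, 2)

  # exhaustive argmin agreement on random ages
  set.seed(12)
  vis <- data.frame(individual_id = rep(sprintf("I%d", 1:6), each = 4),
                    visit = rep(2:5, 6), age = 50 + runif(24, 0, 12))
  smp <- data.frame(sample_id = sprintf("s%d", 1:30),
                    individual_id = sample(sprintf("I%d", 1:6), 30, TRUE),
                    age = 50 + runif(30, 0, 12))
  got <- match_samples_to_visits(smp, vis)
  for (i in seq_len(nrow(smp))) {
    v <- vis[vis$individual_id == smp$individual_id[i], ]
    v <- v[order(v$visit), ]
    expect_equal(got$visit[i], v$visit[which.min(abs(v$age - smp$age[i]))])
  }

  # an individual with samples but no visits is an error listing it
  orphan <- data.frame(sample_id = "z", individual_id = "I99", age = 55)
  expect_error(match_samples_to_visits(orphan, vis), "I99")
})
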