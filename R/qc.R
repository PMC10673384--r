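#' Sample-by-metabolite abundance matrix container
#'
#' Thin S3 container pairing a numeric abundance matrix (samples in rows,
#' metabolites in columns; \code{NA} for missing measurements) with its
#' sample metadata (\code{sample_id}, \code{individual_id}, \code{age},
#' \code{fluid}).
#'
#' @param abund numeric matrix with sample_id rownames and metabolite
#'   colnames.
#' @param meta data.frame aligned with the matrix rows.
#' @return object of class \code{metab_matrix}.
#' @export
metab_matrix <- function(abund, meta) {
  abund <- as.matrix(abund)
  stopifnot(nrow(abund) == nrow(meta), !is.null(colnames(abund)))
  if (is.null(rownames(abund))) rownames(abund) <- meta$sample_id
  if (anyDuplicated(meta$sample_id))
    stop("sample_id values must be unique")
  structure(list(abund = abund, meta = as.data.frame(meta)),
            class = "metab_matrix")
}

#' @export
dim.metab_matrix <- function(x) dim(x$abund)

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("metab_matrix: %d samples x %d metabolites (%s), %.1f%% missing\n",
              nrow(x$abund), ncol(x$abund),
              paste(unique(x$meta$fluid), collapse = "/"),
              100 * mean(is.na(x$abund))))
  invisible(x)
}

subset_metab <- function(x, rows = NULL, cols = NULL) {
  if (!is.null(cols)) x$abund <- x$abund[, cols, drop = FALSE]
  if (!is.null(rows)) {
    x$abund <- x$abund[rows, , drop = FALSE]
    x$meta <- x$meta[rows, , drop = FALSE]
  }
  x
}

#' QC configuration
#'
#' @param metabolite_missingness_threshold metabolites with missing fraction
#'   strictly greater than this are removed (default 0.50).
#' @param sample_missingness_threshold samples with missing fraction
#'   strictly greater than this are removed (default 0.40).
#' @param transform currently only \code{"log10"}.
#' @param impute_half_min if \code{TRUE}, residual missing values after
#'   filtering are imputed as half the metabolite's minimum observed
#'   abundance before transformation (sensitivity mode); default leaves
#'   them missing for complete-case modelling.
#' @return object of class \code{qc_config}.
#' @export
qc_config <- function(metabolite_missingness_threshold = 0.50,
                      sample_missingness_threshold = 0.40,
                      transform = "log10",
                      impute_half_min = FALSE) {
  stopifnot(metabolite_missingness_threshold > 0,
            metabolite_missingness_threshold <= 1,
            sample_missingness_threshold > 0,
            sample_missingness_threshold <= 1,
            transform == "log10")
  structure(list(metabolite_missingness_threshold =
                   metabolite_missingness_threshold,
                 sample_missingness_threshold = sample_missingness_threshold,
                 transform = transform,
                 impute_half_min = impute_half_min),
            class = "qc_config")
}

#' Remove metabolites by missingness
#'
#' A metabolite is removed iff its missing fraction is strictly greater
#' than the threshold (a metabolite at exactly the threshold is retained).
#'
#' @param x a [metab_matrix()].
#' @param threshold fraction in (0, 1].
#' @return list(matrix = filtered metab_matrix, removed = character ids).
#' @export
filter_metabolites_by_missingness <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "metab_matrix"), threshold > 0, threshold <= 1)
  if (ncol(x$abund) == 0 || nrow(x$abund) == 0)
    return(list(matrix = x, removed = character(0)))
  frac <- colMeans(is.na(x$abund))
  removed <- colnames(x$abund)[frac > threshold]
  list(matrix = subset_metab(x, cols = !(colnames(x$abund) %in% removed)),
       removed = removed)
}

#' Remove samples by missingness
#'
#' Row-wise analogue of [filter_metabolites_by_missingness()]: a sample is
#' removed iff its missing fraction across metabolites is strictly greater
#' than the threshold.
#'
#' @inheritParams filter_metabolites_by_missingness
#' @return list(matrix, removed sample ids).
#' @export
filter_samples_by_missingness <- function(x, threshold = 0.4) {
  stopifnot(inherits(x, "metab_matrix"), threshold > 0, threshold <= 1)
  if (ncol(x$abund) == 0 || nrow(x$abund) == 0)
    return(list(matrix = x, removed = character(0)))
  frac <- rowMeans(is.na(x$abund))
  removed <- rownames(x$abund)[frac > threshold]
  list(matrix = subset_metab(x, rows = !(rownames(x$abund) %in% removed)),
       removed = removed)
}

#' Remove zero-IQR (no-variance) metabolites
#'
#' A metabolite is removed iff the interquartile range of its observed
#' (non-missing) values is 0 (type-7 linear-interpolation quantiles).
#' Metabolites with fewer than two observed values are degenerate and are
#' removed as well.
#'
#' @param x a [metab_matrix()].
#' @return list(matrix, removed ids, degenerate ids).
#' @export
filter_zero_iqr <- function(x) {
  stopifnot(inherits(x, "metab_matrix"))
  if (ncol(x$abund) == 0)
    return(list(matrix = x, removed = character(0), degenerate = character(0)))
  n_obs <- colSums(!is.na(x$abund))
  iqr <- apply(x$abund, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::IQR(v, type = 7)
  })
  degenerate <- colnames(x$abund)[n_obs < 2]
  removed <- colnames(x$abund)[n_obs < 2 | iqr == 0]
  list(matrix = subset_metab(x, cols = !(colnames(x$abund) %in% removed)),
       removed = removed, degenerate = degenerate)
}

#' Log10-transform the abundance matrix
#'
#' Element-wise log10 on observed entries; missing values stay missing.
#' Any observed value <= 0 is an error naming the offending metabolite and
#' sample.
#'
#' @param x a [metab_matrix()].
#' @return transformed metab_matrix.
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "metab_matrix"))
  bad <- which(!is.na(x$abund) & x$abund <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive abundance for metabolite '%s' in sample '%s'",
                 colnames(x$abund)[bad[1, 2]], rownames(x$abund)[bad[1, 1]]))
  }
  x$abund <- log10(x$abund)
  x
}

#' Run the full metabolite QC cascade
#'
#' Applies, in order: metabolite-missingness filter, sample-missingness
#' filter, zero-IQR filter, optional half-minimum imputation, and the
#' log10 transform. Returns the processed matrix and an accounting report
#' satisfying
#' \code{final_metabolites == initial - removed_missing - removed_zero_iqr}
#' and \code{final_samples == initial_samples - removed_samples}.
#'
#' @param x a [metab_matrix()] of raw (positive) abundances.
#' @param config a [qc_config()].
#' @return list(matrix = QC'd, log10-scale metab_matrix, report = qc_report).
#' @export
run_qc <- function(x, config = qc_config()) {
  stopifnot(inherits(x, "metab_matrix"), inherits(config, "qc_config"))
  init_m <- ncol(x$abund); init_s <- nrow(x$abund)

  s1 <- filter_metabolites_by_missingness(
    x, config$metabolite_missingness_threshold)
  s2 <- filter_samples_by_missingness(
    s1$matrix, config$sample_missingness_threshold)
  s3 <- filter_zero_iqr(s2$matrix)
  out <- s3$matrix
  if (config$impute_half_min && any(is.na(out$abund))) {
    for (j in seq_len(ncol(out$abund))) {
      mis <- is.na(out$abund[, j])
      if (any(mis)) out$abund[mis, j] <- min(out$abund[!mis, j]) / 2
    }
  }
  out <- log10_transform(out)

  report <- structure(list(
    initial_metabolites = init_m,
    initial_samples = init_s,
    removed_missing_metabolites = length(s1$removed),
    removed_samples = length(s2$removed),
    removed_zero_iqr_metabolites = length(s3$removed),
    final_metabolites = ncol(out$abund),
    final_samples = nrow(out$abund),
    removed_ids = list(missingness = s1$removed,
                       samples = s2$removed,
                       zero_iqr = s3$removed,
                       degenerate = s3$degenerate),
    thresholds = unclass(config)[1:2]
  ), class = "qc_report")
  stopifnot(report$final_metabolites ==
              init_m - report$removed_missing_metabolites -
              report$removed_zero_iqr_metabolites,
            report$final_samples == init_s - report$removed_samples)
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Metabolite QC: %d metabolites x %d samples in\n",
    "  removed %d metabolites (missingness > %g)\n",
    "  removed %d samples (missingness > %g)\n",
    "  removed %d zero-IQR metabolites\n",
    "  => %d metabolites x %d samples, log10 scale\n"),
    x$initial_metabolites, x$initial_samples,
    x$removed_missing_metabolites, x$thresholds[[1]],
    x$removed_samples, x$thresholds[[2]],
    x$removed_zero_iqr_metabolites,
    x$final_metabolites, x$final_samples))
  invisible(x)
}

#' Match fluid samples to study visits by age
#'
#' Each sample is assigned to the visit of the same individual whose
#' recorded age is closest to the sample's age; ties are broken toward the
#' earlier visit.
#'
#' @param samples data.frame with \code{sample_id}, \code{individual_id},
#'   \code{age}.
#' @param visits data.frame with \code{individual_id}, \code{visit},
#'   \code{age}.
#' @return data.frame mapping \code{sample_id} to \code{visit} (plus the
#'   matched visit age and the absolute age gap).
#' @export
match_samples_to_visits <- function(samples, visits) {
  stopifnot(all(c("sample_id", "individual_id", "age") %in% names(samples)),
            all(c("individual_id", "visit", "age") %in% names(visits)))
  missing_ind <- setdiff(samples$individual_id, visits$individual_id)
  if (length(missing_ind) > 0)
    stop(sprintf("individual(s) with samples but no visits: %s",
                 paste(unique(missing_ind), collapse = ", ")))
  visits <- visits[order(visits$individual_id, visits$visit), , drop = FALSE]
  vsplit <- split(visits[, c("visit", "age")], visits$individual_id)
  n <- nrow(samples)
  visit <- integer(n); visit_age <- numeric(n); gap <- numeric(n)
  for (ix in split(seq_len(n), samples$individual_id)) {
    v <- vsplit[[samples$individual_id[ix[1]]]]
    ## visits sorted ascending, so which.min resolves ties toward the
    ## earlier visit
    d <- abs(outer(samples$age[ix], v$age, "-"))
    k <- apply(d, 1, which.min)
    visit[ix] <- v$visit[k]
    visit_age[ix] <- v$age[k]
    gap[ix] <- d[cbind(seq_along(ix), k)]
  }
  data.frame(sample_id = samples$sample_id,
             individual_id = samples$individual_id,
             visit = visit, visit_age = visit_age, age_gap = gap,
             stringsAsFactors = FALSE)
}
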