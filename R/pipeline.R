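#' Baseline descriptive summary of a cohort
#'
#' Tabulates the cohort at its baseline visit: counts and percentages for
#' the categorical variables (sex, race, education, smoking status, BMI
#' category) and mean/SD/median/min/max for the continuous ones (age,
#' CES-D, weekly alcohol, and the four cognitive composites present).
#' Percentages are exact count ratios; when printed to one decimal,
#' round-half-even is used.
#'
#' @param cohort cohort data.frame.
#' @param baseline_visit visit index treated as baseline (default 2).
#' @return list with \code{n}, \code{categorical} (data.frame variable /
#'   level / count / percent) and \code{continuous} (data.frame variable /
#'   mean / sd / median / min / max).
#' @export
descriptive_report <- function(cohort, baseline_visit = 2L) {
  base <- cohort[cohort$visit == baseline_visit, , drop = FALSE]
  if (nrow(base) == 0) stop("no rows at the baseline visit")
  n <- nrow(base)

  cat_vars <- intersect(c("sex", "race", "education", "smoking",
                          "bmi_category"), names(base))
  cat_rows <- do.call(rbind, lapply(cat_vars, function(v) {
    tab <- table(base[[v]])
    data.frame(variable = v, level = names(tab),
               count = as.integer(tab),
               percent = 100 * as.integer(tab) / n,
               stringsAsFactors = FALSE)
  }))

  cont_vars <- intersect(c("age", "cesd", "alcohol_weekly",
                           "PACC3", "IMM", "DEL", "EXE"), names(base))
  cont_rows <- do.call(rbind, lapply(cont_vars, function(v) {
    x <- base[[v]]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  }))
  list(n = n, categorical = cat_rows, continuous = cont_rows)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a metabolite matrix as TSV (abundances + metadata)
#' @param x a [metab_matrix()].
#' @param path_abund,path_meta output file paths.
#' @export
write_metab_matrix <- function(x, path_abund, path_meta) {
  ab <- data.frame(sample_id = rownames(x$abund), x$abund,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(ab, path_abund)
  write_tsv(x$meta, path_meta)
  invisible(x)
}

#' Read a metabolite matrix written by [write_metab_matrix()]
#' @param path_abund,path_meta input file paths.
#' @return a [metab_matrix()].
#' @export
read_metab_matrix <- function(path_abund, path_meta) {
  ab <- utils::read.delim(path_abund, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.delim(path_meta, stringsAsFactors = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab[[1]]
  metab_matrix(m, meta)
}

#' Run the full mediation-screening pipeline
#'
#' Orchestrates the end-to-end workflow on a cohort plus one or more
#' metabolite matrices (or on data simulated from a [sim_config()]):
#' QC -> Step 1 (total effects, reduced-vs-full model choice) -> Step 2
#' (exposure-to-metabolite screen, FDR within fluid) -> Step 3
#' (mediator-to-outcome screen, FDR within fluid x outcome) -> Step 4
#' (product-method decomposition with Monte-Carlo CIs). The cascade only
#' narrows: a metabolite reaches Step 3 only by passing Step 2, and
#' Step 4 only by passing Step 3. An empty survivor set terminates the
#' run cleanly with the stages completed so far.
#'
#' Steps 2-4 use the covariate set chosen in Step 1 (full if any outcome
#' selected the full model). CSF matrices are modelled without the family
#' random intercept.
#'
#' @param cohort cohort data.frame (ignored when \code{sim} is given).
#' @param metabolomes named list of raw [metab_matrix()] objects, names
#'   are fluids ("plasma", "csf").
#' @param sim optional [sim_config()]; when given, the cohort and a
#'   plasma metabolome are generated from it and the truth table is
#'   included in the bundle.
#' @param outcomes outcome columns to analyse.
#' @param qc a [qc_config()].
#' @param fdr_level FDR threshold for Steps 2 and 3.
#' @param reps,alpha Monte-Carlo CI settings for Step 4.
#' @param seed seed for the Monte-Carlo CIs.
#' @param max_visit visits above this index are dropped before analysis.
#' @param min_obs minimum complete-case rows per metabolite model.
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as TSV/JSON.
#' @return list with \code{descriptives}, \code{qc} (per fluid),
#'   \code{step1} (per outcome), \code{step2} (per fluid), \code{step3}
#'   (per fluid x outcome), \code{mediation} (data.frame of Step-4
#'   results), \code{truth} (when simulated), \code{status} and
#'   \code{stopped_at}.
#' @export
run_pipeline <- function(cohort = NULL, metabolomes = NULL, sim = NULL,
                         outcomes = c("PACC3", "IMM", "DEL", "EXE"),
                         qc = qc_config(), fdr_level = 0.05,
                         reps = 1e5, alpha = 0.05, seed = 1L,
                         max_visit = 6L, min_obs = 50L,
                         out_dir = NULL) {
  truth <- NULL
  if (!is.null(sim)) {
    gen <- generate_cohort(sim)
    cohort <- gen$cohort
    truth <- gen$truth
    metabolomes <- list(plasma = generate_metabolome(cohort, truth, sim))
  }
  if (is.null(cohort) || is.null(metabolomes))
    stop("either (cohort, metabolomes) or sim must be supplied")
  need <- c("family_id", "individual_id", "visit", "age", "sex", "race",
            "education", "smoking")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop(sprintf("cohort schema mismatch; missing column(s): %s",
                 paste(miss, collapse = ", ")))

  n_dropped <- sum(cohort$visit > max_visit)
  cohort <- cohort[cohort$visit <= max_visit, , drop = FALSE]

  bundle <- list(status = "ok", stopped_at = NULL,
                 n_visits_dropped = n_dropped, truth = truth,
                 fdr_level = fdr_level, seed = as.integer(seed))
  bundle$descriptives <- descriptive_report(cohort)

  ## QC and visit matching per fluid
  bundle$qc <- list()
  merged <- list()
  for (fl in names(metabolomes)) {
    q <- run_qc(metabolomes[[fl]], qc)
    bundle$qc[[fl]] <- q$report
    merged[[fl]] <- merge_metabolites(cohort, q$matrix)
  }

  ## Step 1: total effects + model choice per outcome
  bundle$step1 <- lapply(outcomes, function(o)
    step1_total_effect(cohort, o, exposure_coding = "categorical"))
  names(bundle$step1) <- outcomes
  choices <- vapply(bundle$step1, `[[`, "", "choice")
  use_full <- any(choices == "full")
  bundle$model_choice <- list(per_outcome = choices, use_full = use_full)

  ## Step 2: exposure -> metabolite, FDR within fluid
  bundle$step2 <- list()
  for (fl in names(merged)) {
    bundle$step2[[fl]] <- step2_metabolite_screen(
      merged[[fl]], fluid = fl, fdr_level = fdr_level, min_obs = min_obs,
      random_family = (fl != "csf"))
  }
  survivors <- lapply(bundle$step2, function(r)
    if (is.null(r)) character(0) else r$metabolite[r$passed])
  if (all(lengths(survivors) == 0)) {
    bundle$status <- "stopped"
    bundle$stopped_at <- "step2: no metabolite passed the FDR gate"
    if (!is.null(out_dir)) write_bundle(bundle, out_dir)
    return(bundle)
  }

  ## Step 3: mediator -> outcome among Step-2 survivors,
  ## FDR within fluid x outcome
  bundle$step3 <- list()
  for (fl in names(merged)) {
    if (length(survivors[[fl]]) == 0) next
    for (o in outcomes) {
      bundle$step3[[paste(fl, o, sep = ".")]] <- step3_outcome_screen(
        merged[[fl]], survivors[[fl]], o, fluid = fl,
        fdr_level = fdr_level, min_obs = min_obs,
        random_family = (fl != "csf"))
    }
  }
  s3 <- do.call(rbind, Filter(Negate(is.null), bundle$step3))
  if (!is.null(s3)) s3 <- s3[s3$passed, , drop = FALSE]
  if (is.null(s3) || nrow(s3) == 0) {
    bundle$status <- "stopped"
    bundle$stopped_at <- "step3: no mediator-outcome pair passed the FDR gate"
    if (!is.null(out_dir)) write_bundle(bundle, out_dir)
    return(bundle)
  }

  ## Step 4: decomposition with Monte-Carlo CIs
  med <- vector("list", nrow(s3))
  for (i in seq_len(nrow(s3))) {
    fl <- s3$fluid[i]; m <- s3$metabolite[i]; o <- s3$outcome[i]
    dat <- merged[[fl]]
    fam <- (fl != "csf")
    fit_a <- fit_lmm(dat, model_spec(m, exposure_coding = "numeric",
                                     full = use_full, random_family = fam))
    fit_out <- fit_lmm(dat, model_spec(o, exposure_coding = "numeric",
                                       full = use_full, metabolite = m,
                                       random_family = fam))
    fit_tot <- fit_lmm(dat, model_spec(o, exposure_coding = "numeric",
                                       full = use_full, random_family = fam))
    med[[i]] <- mediate(fit_a, fit_out, fit_tot, reps = reps, alpha = alpha,
                        seed = seed + i)
    med[[i]]$fluid <- fl
  }
  bundle$mediation <- do.call(rbind, med)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

## serialize every stage's tables; numbers in the report come from these
## artifacts, nothing is recomputed at report time
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(status = bundle$status, stopped_at = bundle$stopped_at,
         fdr_level = bundle$fdr_level, seed = bundle$seed,
         n_visits_dropped = bundle$n_visits_dropped,
         model_choice = bundle$model_choice,
         qc = lapply(bundle$qc, function(r) r[1:7])),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, pretty = TRUE)
  write_tsv(bundle$descriptives$categorical,
            file.path(out_dir, "descriptives_categorical.tsv"))
  write_tsv(bundle$descriptives$continuous,
            file.path(out_dir, "descriptives_continuous.tsv"))
  for (fl in names(bundle$step2))
    if (!is.null(bundle$step2[[fl]]))
      write_tsv(bundle$step2[[fl]],
                file.path(out_dir, sprintf("step2_%s.tsv", fl)))
  for (nm in names(bundle$step3))
    if (!is.null(bundle$step3[[nm]]))
      write_tsv(bundle$step3[[nm]],
                file.path(out_dir, sprintf("step3_%s.tsv", nm)))
  if (!is.null(bundle$mediation))
    write_tsv(bundle$mediation, file.path(out_dir, "step4_mediation.tsv"))
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                         dataframe = "rows", pretty = TRUE)
  invisible(bundle)
}
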