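#' Read a phenotype table
#'
#' Reads a comma-separated UTF-8 phenotype file ("NA" or empty cells as
#' missing) into a typed cohort tibble. Unknown columns are kept with a
#' warning; unparseable numeric cells become missing and are counted in the
#' attached report.
#'
#' @param path CSV file path.
#' @param dictionary Optional named character vector mapping file column
#'   names to canonical cohort names (`c(file_name = "canonical")`).
#' @param required Columns that must be present after renaming.
#' @return A cohort tibble; parsing problems are attached as attribute
#'   `"parse_report"`.
#' @export
read_phenotypes <- function(path, dictionary = NULL,
                            required = c("age", "sex")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(dictionary)) {
    hit <- names(dat) %in% names(dictionary)
    names(dat)[hit] <- unname(dictionary[names(dat)[hit]])
  }
  assert_columns(dat, required, basename(path))
  grp <- cohort_variable_groups()
  known <- c("subject_id", "site", unlist(grp, use.names = FALSE),
             "gfa", "gmd")
  unknown <- setdiff(names(dat), known)
  if (length(unknown)) {
    warning("unknown column(s) kept as-is: ",
            paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  # coerce numeric-typed columns; count newly lost cells
  numcols <- setdiff(intersect(known, names(dat)), c("subject_id", "site"))
  n_bad <- 0L
  for (v in numcols) {
    if (is.numeric(dat[[v]])) next
    was_na <- is.na(dat[[v]])
    coerced <- suppressWarnings(as.numeric(dat[[v]]))
    n_bad <- n_bad + sum(is.na(coerced) & !was_na)
    dat[[v]] <- coerced
  }
  probs <- readr::problems(dat)
  attr(dat, "parse_report") <- list(n_unparseable = n_bad +
                                      if (nrow(probs)) nrow(probs) else 0L,
                                    unknown_columns = unknown)
  dat
}

#' @rdname read_phenotypes
#' @param cohort Cohort tibble to write.
#' @export
write_phenotypes <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order on a simulated (or
#' supplied) cohort: cleaning, the g measurement model, global brain-g
#' associations (bivariate + MIMIC), the four regional scan families, and
#' out-of-sample composite prediction. All result tables are written as
#' TSV and a JSON run report (seeds, ns, fit warnings, FDR families,
#' stage timings) to `out_dir`.
#'
#' @param config A list (or JSON file path) with entries:
#'   \describe{
#'     \item{stages}{subset of `c("simulate","g","global","regional",
#'       "predict")` or `"all"`.}
#'     \item{seed}{integer; required.}
#'     \item{scale}{cohort-size scale factor applied to the default
#'       n = 29,004 (e.g. 0.1 for a fast run); ignored when `input` given.}
#'     \item{input}{optional CSV path of an existing cohort (skips
#'       simulation).}
#'     \item{out_dir}{output directory.}
#'     \item{q}{FDR threshold used in report summaries (default 0.05).}
#'   }
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) {
    stages <- c("simulate", "g", "global", "regional", "predict")
  }
  if (is.null(config$seed) && is.null(config$input)) {
    stop("config$seed is required for stochastic stages", call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 0L)
  qthr <- config$q %||% 0.05
  if (qthr <= 0 || qthr >= 1) stop("q must lie in (0,1)", call. = FALSE)
  out_dir <- config$out_dir %||% "gsembrain_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, seed = seed, stages = list(),
                 package_version = as.character(utils::packageVersion("gsembrain")))
  say <- function(...) message(sprintf(...))
  stamp <- function(stage, t0, extra = list()) {
    report$stages[[stage]] <<- c(list(seconds = round(as.numeric(
      difftime(Sys.time(), t0, units = "secs")), 2)), extra)
  }

  ## cohort ----------------------------------------------------------------
  t0 <- Sys.time()
  if (!is.null(config$input)) {
    cohort <- read_phenotypes(config$input)
    say("read cohort: %d subjects", nrow(cohort))
  } else {
    scale <- config$scale %||% 1
    spec <- default_population_spec(n = max(200L, round(29004 * scale)))
    cohort <- generate_cohort(spec, seed = seed)
    write_phenotypes(cohort, file.path(out_dir, "cohort.csv"))
    write_population_spec(spec, file.path(out_dir, "population_spec.json"))
    say("simulated cohort: %d subjects (seed %d)", nrow(cohort), seed)
  }
  cleaned <- clean_cohort(cohort)
  cohort <- cleaned$cohort
  readr::write_tsv(cleaned$report, file.path(out_dir, "cleaning_report.tsv"))
  stamp("simulate", t0, list(n = nrow(cohort),
                             n_cells_trimmed = sum(cleaned$report$n_outlier_removed)))

  ## g measurement ---------------------------------------------------------
  if ("g" %in% stages) {
    t0 <- Sys.time()
    gmod_raw <- fit_g_cfa(cohort, covariates = character())
    gmod <- fit_g_cfa(cohort)
    pca <- pca_first_component(cohort[, cognitive_tests()])
    cohort <- derive_gfa_gmd(cohort)
    readr::write_tsv(tidy(gmod), file.path(out_dir, "g_cfa_parameters.tsv"))
    stamp("g", t0, list(
      variance_explained_uncorrected = gmod_raw$variance_explained,
      variance_explained_corrected = gmod$variance_explained,
      pairs_added = vapply(gmod$pairs_added, paste, "", collapse = "~~"),
      pca_variance_proportion = pca$variance_proportion,
      fit = as.list(glance(gmod))))
    say("g CFA: %.0f%% variance (corrected: %.0f%%)",
        100 * gmod_raw$variance_explained, 100 * gmod$variance_explained)
  }

  ## global associations ---------------------------------------------------
  if ("global" %in% stages) {
    t0 <- Sys.time()
    if (!("gfa" %in% names(cohort))) cohort <- derive_gfa_gmd(cohort)
    glob <- global_brain_g(cohort)
    mim <- mimic_global(cohort)
    readr::write_tsv(glob, file.path(out_dir, "global_individual.tsv"))
    readr::write_tsv(mim$associations, file.path(out_dir, "global_mimic.tsv"))
    stamp("global", t0, list(
      individual = setNames(as.list(glob$beta), glob$variable),
      mimic_r2 = mim$r2,
      mimic_pairs_added = length(mim$pairs_added),
      n_significant_q = sum(glob$q < qthr, na.rm = TRUE)))
    say("global scan: TBV beta = %.3f", glob$beta[glob$variable == "tbv"])
  }

  ## regional scans --------------------------------------------------------
  if ("regional" %in% stages) {
    t0 <- Sys.time()
    fams <- c("cortical", "fa", "md", "subcortical")
    counts <- list()
    for (f in fams) {
      tab <- regional_scan(cohort, f)
      readr::write_tsv(tab, file.path(out_dir, paste0("regional_", f, ".tsv")))
      counts[[f]] <- list(n_tests = nrow(tab),
                          n_significant_q = sum(tab$q < qthr, na.rm = TRUE))
      if (f == "fa") fa_tab <- tab
      if (f == "md") md_tab <- tab
    }
    cls <- tract_class_summary(dplyr::bind_rows(fa_tab, md_tab))
    readr::write_tsv(cls, file.path(out_dir, "tract_class_summary.tsv"))
    stamp("regional", t0, c(counts, list(
      class_means = setNames(as.list(cls$mean_beta),
                             paste(cls$class, cls$modality, sep = "_")))))
    say("regional scans: %s tests",
        paste(vapply(counts, function(x) x$n_tests, 1), collapse = "+"))
  }

  ## out-of-sample prediction ---------------------------------------------
  if ("predict" %in% stages) {
    t0 <- Sys.time()
    train <- cohort[cohort$site == "manchester", , drop = FALSE]
    evals <- list()
    for (f in c("fa", "md", "cortical", "subcortical")) {
      cm <- train_composite(train, f)
      write_composite_model(cm, file.path(out_dir,
                                          paste0("composite_", f, ".json")))
      ev <- evaluate_composite(cohort, cm, test_site = "newcastle")
      evals[[f]] <- tibble::as_tibble(ev)
    }
    pred <- dplyr::bind_rows(evals)
    readr::write_tsv(pred, file.path(out_dir, "prediction.tsv"))
    stamp("predict", t0, list(
      estimates = setNames(as.list(pred$beta),
                           paste(pred$roi_family, pred$role, sep = "_"))))
    say("prediction: %d family x site estimates", nrow(pred))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
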