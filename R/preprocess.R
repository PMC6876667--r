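#' Clean a raw cohort table
#'
#' Applies the study's three cleaning rules, in one pass:
#' \enumerate{
#'   \item values beyond +/- 4 SD of a variable's raw mean are set missing,
#'     for all brain and cognitive measures (covariates are untouched);
#'   \item Trail-Making part B times coded 0 ("trail not completed") are
#'     set missing;
#'   \item normal-appearing white matter is recomputed as `wm - wmh`;
#'     negative differences are flagged and set missing.
#' }
#' The +/- 4 SD screen uses means/SDs computed once on the raw (pre-trim)
#' distribution, so the operation is idempotent.
#'
#' @param raw A cohort tibble (see [generate_cohort()] for the roster).
#' @return A list with elements `cohort` (cleaned tibble) and `report`
#'   (a `cleaning_report` tibble: per-variable counts of cells set missing
#'   by each rule, plus the number of NAWM values derived).
#' @export
#' @examples
#' cleaned <- clean_cohort(generate_cohort(default_population_spec(500), 1))
#' cleaned$report
clean_cohort <- function(raw) {
  grp <- cohort_variable_groups()
  targets <- intersect(
    c(grp$cognitive, grp$global, grp$fa, grp$md, grp$cortical, grp$subcortical),
    names(raw)
  )
  assert_columns(raw, c("tmtb_time", "wm", "wmh"), "cohort")
  out <- raw

  # rule 2: zero-coded Trail-Making times
  zero_tmtb <- sum(out$tmtb_time == 0, na.rm = TRUE)
  out$tmtb_time[!is.na(out$tmtb_time) & out$tmtb_time == 0] <- NA_real_

  # rule 1: +/- 4 SD outlier screen, moments computed once on the raw
  # distribution. A cleaned cohort carries its trim bounds so re-cleaning
  # reuses them (idempotence). NAWM is trimmed last, after re-derivation.
  bounds <- attr(raw, "trim_bounds")
  if (is.null(bounds)) bounds <- list()
  outlier_counts <- integer(length(targets))
  names(outlier_counts) <- targets
  trim <- function(v) {
    x <- out[[v]]
    if (is.null(bounds[[v]])) {
      mu <- mean(x, na.rm = TRUE)
      s <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(s) || s == 0) return(invisible())
      bounds[[v]] <<- c(mu - 4 * s, mu + 4 * s)
    }
    bad <- !is.na(x) & (x < bounds[[v]][1] | x > bounds[[v]][2])
    outlier_counts[[v]] <<- sum(bad)
    x[bad] <- NA_real_
    out[[v]] <<- x
  }
  for (v in setdiff(targets, "nawm")) trim(v)

  # rule 3: derive NAWM from the trimmed wm/wmh, then screen it too
  both <- !is.na(out$wm) & !is.na(out$wmh)
  nawm_new <- out$wm - out$wmh
  neg <- both & nawm_new < 0
  nawm_new[neg] <- NA_real_
  out$nawm <- ifelse(both, nawm_new, NA_real_)
  n_derived <- sum(both & !neg)
  if (any(neg)) {
    warning(sprintf("%d subject(s) with wm < wmh; nawm set missing", sum(neg)))
  }
  if (!("nawm" %in% targets)) targets <- c(targets, "nawm")
  trim("nawm")
  attr(out, "trim_bounds") <- bounds

  report <- tibble::tibble(
    variable = targets,
    n_outlier_removed = as.integer(outlier_counts[targets]),
    n_zero_coded = ifelse(targets == "tmtb_time", zero_tmtb, 0L),
    n_negative_nawm = ifelse(targets == "nawm", sum(neg), 0L)
  )
  attr(report, "n_nawm_derived") <- n_derived
  class(report) <- c("cleaning_report", class(report))
  list(cohort = out, report = report)
}

#' Split a cohort into middle-aged and older groups
#'
#' Splits the sample at the age that halves the cognitive-MRI overlap set
#' (by default: subjects with grey-matter volume and at least one cognitive
#' test), so both groups have equal statistical power for brain-g models.
#' For an odd-sized overlap set the middle-aged group receives the extra
#' subject; subjects exactly at the boundary go to the middle-aged group.
#' Subjects outside the eligible set are assigned by the same boundary.
#'
#' @param cohort A cohort tibble with an `age` column.
#' @param eligible Optional logical vector marking the overlap set; the
#'   default rule requires non-missing `gm` and at least one of the four
#'   cognitive tests.
#' @return A list with `middle` and `older` tibbles and the numeric
#'   `boundary` (years).
#' @export
age_split <- function(cohort, eligible = NULL) {
  assert_columns(cohort, "age", "cohort")
  if (any(is.na(cohort$age))) {
    stop("age must be observed for all subjects", call. = FALSE)
  }
  if (is.null(eligible)) {
    grp <- cohort_variable_groups()
    cog <- intersect(grp$cognitive, names(cohort))
    any_cog <- rowSums(!is.na(cohort[, cog, drop = FALSE])) > 0
    eligible <- if ("gm" %in% names(cohort)) !is.na(cohort$gm) & any_cog else any_cog
  }
  ages <- cohort$age[eligible]
  if (length(unique(ages)) < 2) {
    stop("degenerate age distribution: cannot split", call. = FALSE)
  }
  srt <- sort(ages)
  k <- ceiling(length(srt) / 2)          # odd n: middle group gets n+1
  boundary <- srt[k]
  middle <- cohort$age <= boundary
  list(middle = cohort[middle, , drop = FALSE],
       older = cohort[!middle, , drop = FALSE],
       boundary = boundary)
}
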