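as_association_table <- function(x, family) {
  attr(x, "family") <- family
  class(x) <- c("association_table", class(x))
  x
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table> family = %s (%d tests)\n",
              attr(x, "family"), nrow(x)))
  NextMethod()
}

regional_family_columns <- function(family) {
  grp <- cohort_variable_groups()
  switch(family,
         cortical = grp$cortical,
         subcortical = grp$subcortical,
         fa = grp$fa,
         md = grp$md,
         stop("unknown family: ", family, call. = FALSE))
}

#' Regional brain-g association scan
#'
#' One bivariate FIML SEM per region (same contract as
#' [bivariate_brain_g()]) across a family of regional measures: 96 cortical
#' volumes, 27 FA tracts, 27 MD tracts or 14 subcortical volumes.
#' Benjamini-Hochberg FDR is applied within the family. Effect signs are
#' stored as estimated (any valence flipping is presentation-only).
#' A region whose model fails to converge is recorded (`beta = NA`,
#' `error` message) and the scan continues.
#'
#' @inheritParams bivariate_brain_g
#' @param family `"cortical"`, `"fa"`, `"md"` or `"subcortical"`.
#' @param regions Optional subset of the family's columns.
#' @return An `association_table` tibble: one row per region with `beta`,
#'   `se`, `p`, `q`, `n`, `family`.
#' @export
regional_scan <- function(cohort, family = c("cortical", "fa", "md",
                                             "subcortical"),
                          covariates = c("age", "sex"),
                          mri_covariates = default_mri_covariates(),
                          regions = NULL) {
  family <- match.arg(family)
  cols <- intersect(regional_family_columns(family), names(cohort))
  if (!is.null(regions)) cols <- intersect(cols, regions)
  if (!length(cols)) stop("no ", family, " columns present", call. = FALSE)
  rows <- purrr::map(cols, function(v) {
    tryCatch({
      r <- bivariate_brain_g(cohort, v, covariates, mri_covariates)
      attr(r, "fit") <- NULL
      r$error <- NA_character_
      r
    }, error = function(e) tibble::tibble(
      variable = v, beta = NA_real_, se = NA_real_, p = NA_real_,
      model = "individual", group = "all", n = NA_integer_,
      error = conditionMessage(e)))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out$family <- family
  as_association_table(out, family)
}

#' Tract-class summaries of regional associations
#'
#' Arithmetic mean of the standardized associations per tract class
#' (thalamic radiations; association fibres incl. forceps minor;
#' projection fibres incl. forceps major), per modality.
#'
#' @param table An `association_table` from [regional_scan()] with family
#'   `"fa"` or `"md"` (or a row-bound combination).
#' @param classes Tract-to-class mapping; defaults to [tract_classes()].
#' @return Tibble with `class`, `modality`, `mean_beta`, `n_tracts`.
#' @export
tract_class_summary <- function(table, classes = tract_classes()) {
  lut <- dplyr::bind_rows(
    tibble::tibble(variable = classes$fa_variable, class = classes$class,
                   modality = "fa"),
    tibble::tibble(variable = classes$md_variable, class = classes$class,
                   modality = "md")
  )
  joined <- dplyr::left_join(table, lut, by = "variable")
  if (any(is.na(joined$class))) {
    stop("tract(s) without class assignment: ",
         paste(joined$variable[is.na(joined$class)], collapse = ", "),
         call. = FALSE)
  }
  joined |>
    dplyr::group_by(.data$class, .data$modality) |>
    dplyr::summarise(mean_beta = mean(.data$beta, na.rm = TRUE),
                     n_tracts = dplyr::n(), .groups = "drop")
}

#' Forest plot of an association table
#'
#' Standardized associations with 95% confidence intervals, ordered by
#' effect size; FDR-significant regions are filled.
#'
#' @param object An `association_table`.
#' @param q_threshold FDR significance threshold for the fill aesthetic.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot association_table
#' @export
autoplot.association_table <- function(object, q_threshold = 0.05, ...) {
  d <- dplyr::filter(object, !is.na(.data$beta))
  d$significant <- !is.na(d$q) & d$q < q_threshold
  d$variable <- stats::reorder(d$variable, d$beta)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               name = sprintf("q < %.2f", q_threshold)) +
    ggplot2::labs(x = "standardized association with g", y = NULL,
                  title = sprintf("Family: %s", attr(object, "family"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
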