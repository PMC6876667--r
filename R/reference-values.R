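#' Published reference estimates emulated by the synthetic cohort
#'
#' Standardised estimates reported by the large UK Biobank
#' brain-structure/intelligence study that this package's synthetic cohort
#' generator emulates. These values serve two purposes: they are the
#' population parameters of [default_population_spec()], and they are the
#' printed worked-example inputs for desk-check utilities such as
#' [variance_explained()] and [congruence()].
#'
#' @return A named list with elements:
#' \describe{
#'   \item{loadings_uncorrected}{standardised g loadings of the four
#'     cognitive tests without age/sex correction.}
#'   \item{loadings_corrected}{standardised loadings with age and sex
#'     applied to the manifest variables inside the model.}
#'   \item{resid_corr}{standardised residual covariance between Matrix
#'     Reasoning and Verbal-Numerical Reasoning.}
#'   \item{loadings_middle, loadings_older}{freely estimated group
#'     loadings from the age-split weak-invariance models.}
#'   \item{global_paths}{standardised bivariate g associations for the six
#'     global MRI measures (TBV, GM, NAWM, WMH, gFA, gMD).}
#'   \item{sample}{key sample figures: total n, MRI/cognitive overlap,
#'     subjects with at least one cognitive test, age distribution and the
#'     age-split boundary.}
#' }
#' @export
#' @examples
#' ref <- reference_estimates()
#' variance_explained(ref$loadings_uncorrected)
reference_estimates <- function() {
  list(
    loadings_uncorrected = c(matrix_reasoning = 0.550, symbol_digit = 0.626,
                             vnr = 0.532, tmtb_time = -0.794),
    loadings_corrected = c(matrix_reasoning = 0.505, symbol_digit = 0.479,
                           vnr = 0.592, tmtb_time = -0.666),
    resid_corr = 0.170,
    loadings_middle = c(matrix_reasoning = 0.506, symbol_digit = 0.539,
                        vnr = 0.614, tmtb_time = -0.719),
    loadings_older = c(matrix_reasoning = 0.522, symbol_digit = 0.492,
                       vnr = 0.569, tmtb_time = -0.701),
    global_paths = c(tbv = 0.276, gm = 0.281, nawm = 0.246,
                     wmh = -0.106, gfa = 0.090, gmd = -0.066),
    sample = list(n = 29004L, overlap_mri_cog = 18426L, n_any_cog = 27100L,
                  age_mean = 63.13, age_sd = 7.48, age_min = 44, age_max = 81,
                  age_split = 63.29)
  )
}

# ---------------------------------------------------------------------------
# Region rosters. Column-name conventions follow the Harvard-Oxford cortical
# atlas and the AutoPtx tract set; no atlas computation is performed here.
# The `beta` column is the default population g association used by the
# generator (anchored to the printed regional estimates; interpolated where
# only ranges/summaries were printed).
# ---------------------------------------------------------------------------

cortical_roster_values <- function() {
  # 48 Harvard-Oxford cortical regions; left/right generating associations.
  v <- c(
    frontal_pole               = 0.206, insula                     = 0.194,
    superior_frontal           = 0.150, middle_frontal             = 0.140,
    ifg_triangularis           = 0.120, ifg_opercularis            = 0.122,
    precentral                 = 0.110, temporal_pole              = 0.152,
    stg_anterior               = 0.140, stg_posterior              = 0.115,
    mtg_anterior               = 0.132, mtg_posterior              = 0.105,
    mtg_temporooccipital       = 0.095, itg_anterior               = 0.118,
    itg_posterior              = 0.096, itg_temporooccipital       = 0.085,
    postcentral                = 0.090, superior_parietal          = 0.100,
    smg_anterior               = 0.082, smg_posterior              = 0.078,
    angular                    = 0.095, lat_occipital_superior     = 0.156,
    lat_occipital_inferior     = 0.120, intracalcarine             = 0.070,
    frontal_medial             = 0.130, juxtapositional            = 0.105,
    subcallosal                = 0.166, paracingulate              = 0.160,
    cingulate_anterior         = 0.120, cingulate_posterior        = 0.110,
    precuneous                 = 0.130, cuneal                     = 0.080,
    frontal_orbital            = 0.190, parahippocampal_anterior   = 0.145,
    parahippocampal_posterior  = 0.098, lingual                    = 0.112,
    temp_fusiform_anterior     = 0.135, temp_fusiform_posterior    = 0.108,
    temp_occ_fusiform          = 0.100, occipital_fusiform         = 0.085,
    frontal_operculum          = 0.125, central_operculum          = 0.115,
    parietal_operculum         = 0.085, planum_polare              = 0.110,
    heschls                    = 0.095, planum_temporale           = 0.092,
    supracalcarine             = 0.066, occipital_pole             = 0.075
  )
  # right-hemisphere values perturbed slightly (printed anchors where given)
  right <- v - 0.003
  right["frontal_pole"] <- 0.216
  right["insula"] <- 0.205
  right["subcallosal"] <- 0.170
  right["precuneous"] <- 0.132
  tibble::tibble(
    structure = rep(names(v), each = 2L),
    hemi = rep(c("l", "r"), times = length(v)),
    beta = as.numeric(rbind(v, right[names(v)])),
    variable = paste0("cortical_", rep(names(v), each = 2L), "_",
                      rep(c("l", "r"), times = length(v)))
  )
}

subcortical_roster_values <- function() {
  left <- c(accumbens = 0.105, amygdala = 0.075, caudate = 0.150,
            hippocampus = 0.140, pallidum = 0.115, putamen = 0.160,
            thalamus = 0.251)
  right <- c(accumbens = 0.110, amygdala = 0.062, caudate = 0.155,
             hippocampus = 0.135, pallidum = 0.120, putamen = 0.165,
             thalamus = 0.256)
  tibble::tibble(
    structure = rep(names(left), each = 2L),
    hemi = rep(c("l", "r"), times = length(left)),
    beta = as.numeric(rbind(left, right)),
    variable = paste0("subcortical_", rep(names(left), each = 2L), "_",
                      rep(c("l", "r"), times = length(left)))
  )
}

tract_roster_values <- function() {
  # 27 AutoPtx tracts: 12 bilateral pairs plus forceps minor/major and the
  # middle cerebellar peduncle. Classes follow the conventional grouping:
  # thalamic radiations; association fibres incl. forceps minor; projection
  # fibres incl. forceps major.
  def <- function(tract, hemi, class, fa, md) {
    tibble::tibble(tract = tract, hemi = hemi, class = class,
                   beta_fa = fa, beta_md = md)
  }
  dplyr::bind_rows(
    def("atr",  "l", "thalamic",    0.095, -0.100),
    def("atr",  "r", "thalamic",    0.090, -0.098),
    def("str",  "l", "thalamic",    0.075, -0.092),
    def("str",  "r", "thalamic",    0.072, -0.090),
    def("ptr",  "l", "thalamic",    0.070, -0.086),
    def("ptr",  "r", "thalamic",    0.066, -0.080),
    def("cing", "l", "association", 0.035, -0.025),
    def("cing", "r", "association", 0.030, -0.020),
    def("cingph", "l", "association", 0.028, -0.018),
    def("cingph", "r", "association", 0.022,  0.000),
    def("ifof", "l", "association", 0.090, -0.075),
    def("ifof", "r", "association", 0.085, -0.070),
    def("ilf",  "l", "association", 0.070, -0.055),
    def("ilf",  "r", "association", 0.066, -0.052),
    def("slf",  "l", "association", 0.078, -0.058),
    def("slf",  "r", "association", 0.074, -0.054),
    def("unc",  "l", "association", 0.058, -0.040),
    def("unc",  "r", "association", 0.053, -0.036),
    def("fmin", NA_character_, "association", 0.110, -0.095),
    def("ar",   "l", "projection",  0.012, -0.010),
    def("ar",   "r", "projection",  0.035, -0.030),
    def("cst",  "l", "projection",  0.060, -0.065),
    def("cst",  "r", "projection",  0.065, -0.075),
    def("ml",   "l", "projection",  0.030,  0.005),
    def("ml",   "r", "projection",  0.028,  0.007),
    def("mcp",  NA_character_, "projection", 0.015, -0.020),
    def("fmaj", NA_character_, "projection", 0.045, -0.005)
  ) |>
    dplyr::mutate(
      stem = ifelse(is.na(.data$hemi), .data$tract,
                    paste0(.data$tract, "_", .data$hemi)),
      fa_variable = paste0("fa_", .data$stem),
      md_variable = paste0("md_", .data$stem)
    )
}

#' White-matter tract class assignments
#'
#' The mapping from the 27 AutoPtx tract-averaged measures to the three
#' conventional tract classes used in class-level summaries: thalamic
#' radiations, association fibres (including the forceps minor) and
#' projection fibres (including the forceps major). The table is plain data
#' and can be edited/overridden before being passed to
#' [tract_class_summary()].
#'
#' @return A tibble with columns `tract`, `hemi`, `class`, `fa_variable`,
#'   `md_variable`.
#' @export
tract_classes <- function() {
  tract_roster_values() |>
    dplyr::select("tract", "hemi", "class", "fa_variable", "md_variable")
}

# Convenience accessors used across modules -------------------------------

cohort_variable_groups <- function() {
  ct <- cortical_roster_values()
  sc <- subcortical_roster_values()
  tr <- tract_roster_values()
  list(
    cognitive = c("matrix_reasoning", "symbol_digit", "vnr", "tmtb_time"),
    global = c("tbv", "gm", "wm", "wmh", "nawm"),
    covariates = c("age", "sex", "head_x", "head_y", "head_z"),
    fa = tr$fa_variable,
    md = tr$md_variable,
    cortical = ct$variable,
    subcortical = sc$variable
  )
}
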