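#' Build a structural-equation model specification
#'
#' Parses a small declarative model syntax into a validated model object
#' with a fully enumerated parameter table, so the free-parameter count and
#' degrees of freedom are computable before fitting.
#'
#' Syntax (one statement per line, `#` comments allowed):
#' \describe{
#'   \item{`f =~ y1 + y2 + y3`}{latent `f` measured by the listed
#'     indicators (all loadings free; latent scale identified by fixing the
#'     latent (residual) variance to 1).}
#'   \item{`y ~ x1 + x2`}{directed regression paths.}
#'   \item{`y1 ~~ y2`}{a (residual) covariance; `y ~~ 0.3*y2` fixes it.}
#' }
#' A numeric prefix (`0.5*x`) fixes the corresponding parameter. Variables
#' never appearing on the left of `~`/`=~` are exogenous; their variances,
#' covariances and means are free model parameters (their block is
#' saturated). Every endogenous observed variable gets a free residual
#' variance and a free intercept; latent means are fixed to 0.
#'
#' @param syntax Model syntax string.
#' @param covariates Character vector naming the exogenous observed
#'   variables to treat as covariates: they are exempted from the
#'   standardized ("nox") solution metric, and their regressions are never
#'   subject to cross-group equality constraints.
#' @return A `gsem_model` object.
#' @export
#' @examples
#' m <- build_model("g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time
#'                   matrix_reasoning ~~ vnr")
#' m
build_model <- function(syntax, covariates = character()) {
  st <- parse_model_syntax(syntax)
  latents <- unique(st$lhs[st$op == "=~"])
  vars <- unique(c(st$lhs, st$rhs))
  observed <- setdiff(vars, latents)
  undeclared <- setdiff(latents, st$lhs[st$op == "=~"])
  if (length(undeclared)) {
    stop("latent variable(s) without indicators: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  all_vars <- c(observed, latents)
  idx <- function(v) match(v, all_vars)

  # directed edges: A[target, source]
  a_rows <- st[st$op %in% c("=~", "~"), , drop = FALSE]
  a_edges <- tibble::tibble(
    target = ifelse(a_rows$op == "=~", a_rows$rhs, a_rows$lhs),
    source = ifelse(a_rows$op == "=~", a_rows$lhs, a_rows$rhs),
    fixed = a_rows$fixed,
    class = dplyr::case_when(
      a_rows$op == "=~" ~ "loading",
      a_rows$rhs %in% covariates ~ "covariate",
      TRUE ~ "regression"
    )
  )
  if (anyDuplicated(paste(a_edges$target, a_edges$source))) {
    stop("duplicate path specification", call. = FALSE)
  }
  # cycle check on directed graph
  check_acyclic(a_edges, all_vars)

  endo <- unique(a_edges$target)
  exo <- setdiff(all_vars, endo)
  exo_obs <- intersect(exo, observed)

  ptab <- list()
  add <- function(matrix, row, col, class, free, value, label) {
    lhs_name <- row
    rhs_name <- col
    row_idx <- idx(row)
    col_idx <- idx(col)
    ptab[[length(ptab) + 1]] <<- tibble::tibble(
      matrix = matrix, row = row_idx, col = col_idx,
      lhs = lhs_name, rhs = rhs_name,
      class = class, free = free, value = value, label = label)
  }

  for (k in seq_len(nrow(a_edges))) {
    e <- a_edges[k, ]
    add("A", e$target, e$source, e$class, is.na(e$fixed),
        ifelse(is.na(e$fixed), if (e$class == "loading") 0.5 else 0, e$fixed),
        paste0(e$source, if (e$class == "loading") "=~" else "~>", e$target))
  }
  # explicit covariances
  c_rows <- st[st$op == "~~", , drop = FALSE]
  for (k in seq_len(nrow(c_rows))) {
    e <- c_rows[k, ]
    add("S", e$lhs, e$rhs, "rescov", is.na(e$fixed),
        ifelse(is.na(e$fixed), 0, e$fixed),
        paste0(e$lhs, "~~", e$rhs))
  }
  # residual variances for endogenous observed; latent (residual) variance
  # fixed to 1 (identification: latent scale = unit variance)
  for (v in intersect(endo, observed)) {
    add("S", v, v, "resvar", TRUE, 0.5, paste0(v, "~~", v))
  }
  for (v in latents) {
    add("S", v, v, "latvar", FALSE, 1, paste0(v, "~~", v))
  }
  # exogenous observed block: saturated covariance + means
  if (length(exo_obs)) {
    for (i in seq_along(exo_obs)) {
      for (j in seq_len(i)) {
        add("S", exo_obs[i], exo_obs[j],
            ifelse(i == j, "exovar", "exocov"),
            TRUE, ifelse(i == j, 1, 0),
            paste0(exo_obs[j], "~~", exo_obs[i]))
      }
    }
    for (v in exo_obs) add("M", v, v, "exomean", TRUE, 0, paste0(v, "~1"))
  }
  # intercepts for endogenous observed; latent means fixed 0
  for (v in intersect(endo, observed)) {
    add("M", v, v, "intercept", TRUE, 0, paste0(v, "~1"))
  }
  for (v in latents) add("M", v, v, "latmean", FALSE, 0, paste0(v, "~1"))

  ptab <- dplyr::bind_rows(ptab)
  out <- list(syntax = syntax, observed = observed, latents = latents,
              all = all_vars, covariates = intersect(covariates, observed),
              ptab = ptab)
  class(out) <- "gsem_model"
  out
}

parse_model_syntax <- function(syntax) {
  lines <- unlist(strsplit(syntax, "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model syntax", call. = FALSE)
  parse_rhs <- function(x) {
    terms <- trimws(unlist(strsplit(x, "\\+")))
    fixed <- rep(NA_real_, length(terms))
    star <- grepl("\\*", terms)
    fixed[star] <- as.numeric(sub("\\*.*$", "", terms[star]))
    terms[star] <- trimws(sub("^.*\\*", "", terms[star]))
    list(terms = terms, fixed = fixed)
  }
  rows <- list()
  for (ln in lines) {
    op <- if (grepl("=~", ln)) "=~" else if (grepl("~~", ln)) "~~"
          else if (grepl("~", ln)) "~" else
            stop("cannot parse model line: ", ln, call. = FALSE)
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse model line: ", ln, call. = FALSE)
    lhs <- trimws(parts[1])
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", lhs)) {
      stop("invalid variable name: ", lhs, call. = FALSE)
    }
    rr <- parse_rhs(parts[2])
    rows[[length(rows) + 1]] <- tibble::tibble(
      op = op, lhs = lhs, rhs = rr$terms, fixed = rr$fixed)
  }
  dplyr::bind_rows(rows)
}

check_acyclic <- function(a_edges, all_vars) {
  adj <- lapply(all_vars, function(v) a_edges$target[a_edges$source == v])
  names(adj) <- all_vars
  state <- setNames(rep(0L, length(all_vars)), all_vars)  # 0 new 1 open 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("cyclic path through ", v, call. = FALSE)
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in all_vars) visit(v)
  invisible(TRUE)
}

#' Count free parameters and model degrees of freedom
#'
#' @param model A `gsem_model`.
#' @param ngroups Number of groups (constraint handling is applied at fit
#'   time; this counts the single-group template).
#' @return A list with `n_free`, `n_moments` and `df` for a single-group
#'   fit of the template.
#' @export
count_parameters <- function(model, ngroups = 1) {
  p <- length(model$observed)
  n_free <- length(unique(model$ptab$label[model$ptab$free]))
  n_moments <- p * (p + 3) / 2
  list(n_free = n_free * ngroups, n_moments = n_moments * ngroups,
       df = (n_moments - n_free) * ngroups)
}

#' @export
print.gsem_model <- function(x, ...) {
  cnt <- count_parameters(x)
  cat("<gsem_model>\n")
  cat("  observed:", length(x$observed), " latent:", length(x$latents), "\n")
  cat("  free parameters:", cnt$n_free, " df:", cnt$df, "\n")
  invisible(x)
}
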