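#' Log-transform a positive marker vector
#'
#' Natural log, elementwise. MTV, chromogranin A and gamma-GT are right
#' skewed, so they enter the survival models on the log scale. The log base
#' only shifts and scales the values, and z-standardization removes both, so
#' the downstream composite is base-invariant.
#'
#' @param x Numeric marker values, all `> 0`.
#' @param ids Optional patient identifiers used in error messages.
#' @return `log(x)`.
#' @export
log_transform <- function(x, ids = NULL) {
  if (length(x) == 0L) return(numeric(0))
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    abort(sprintf("Log-transform requires positive values; offending patient(s): %s.", who),
      class = "mtvsurv_domain_error")
  }
  log(x)
}

#' z-standardize a marker vector
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (n - 1), so
#' the output has mean 0 and sample SD 1 on the cohort it is computed on.
#'
#' @param x Numeric values, length >= 2, with nonzero spread.
#' @return Standardized values.
#' @export
z_standardize <- function(x) {
  if (length(x) < 2L || anyNA(x)) {
    abort("z-standardization needs >= 2 complete values.",
      class = "mtvsurv_invalid_argument")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Cannot z-standardize a constant vector.",
      class = "mtvsurv_degenerate_spread")
  }
  (x - mean(x)) / s
}

#' Composite MTV / chromogranin A prognostic score
#'
#' MTV (an imaging tumor-burden marker) and chromogranin A (a blood
#' tumor-burden marker) are strongly correlated and individually violate
#' proportional hazards, so they are combined into a single predictor: each
#' is log-transformed, z-standardized on the cohort, and the two z-scores
#' are averaged:
#' `score = 0.5 * (z(log(mtv)) + z(log(cga)))`.
#'
#' The score is unit-invariant: rescaling all MTV (or all CgA) values by any
#' positive constant shifts the logs and the z-step removes the shift.
#'
#' @param mtv Baseline MTV values, ml, all `> 0`.
#' @param cga Chromogranin A values, ug/l, all `> 0`; same length and
#'   patient order as `mtv`.
#' @param ids Optional patient identifiers for error messages.
#' @return Numeric composite scores with cohort mean 0.
#' @seealso [add_composite()] for the data-frame interface.
#' @export
composite_score <- function(mtv, cga, ids = NULL) {
  if (length(mtv) != length(cga)) {
    abort("`mtv` and `cga` must be aligned vectors of equal length.",
      class = "mtvsurv_alignment_error")
  }
  0.5 * (z_standardize(log_transform(mtv, ids)) +
         z_standardize(log_transform(cga, ids)))
}

#' Append the composite MTV/CgA score to a cohort table
#'
#' @param data Cohort data frame.
#' @param mtv,cga Columns holding baseline MTV (ml) and chromogranin A
#'   (ug/l), tidyselect-style. Defaults `mtv_ml` and `cga`.
#' @param name Name of the appended column. Default `"mtv_cga_composite"`.
#' @return `data` as a tibble with the composite column appended.
#' @examples
#' tibble::tibble(id = 1:4, mtv_ml = c(10, 40, 160, 640),
#'                cga = c(90, 300, 1500, 5000)) |>
#'   add_composite()
#' @export
add_composite <- function(data, mtv = "mtv_ml", cga = "cga",
                          name = "mtv_cga_composite") {
  m <- dplyr::pull(data, {{ mtv }})
  g <- dplyr::pull(data, {{ cga }})
  ids <- if ("id" %in% names(data)) data$id else NULL
  as_tibble(data) |>
    dplyr::mutate({{ name }} := composite_score(m, g, ids))
}
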