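#' Relative MTV change between baseline and interim scans
#'
#' `100 * (interim - baseline) / baseline`. A zero baseline has no defined
#' relative change and raises an error: such patients must be handled
#' explicitly by the caller.
#'
#' @param baseline_mtv Baseline MTV, ml (`> 0`). Vectorized.
#' @param interim_mtv Interim MTV, ml (`>= 0`). Vectorized.
#' @return Percent change (negative = shrinkage).
#' @examples
#' percent_change(100, 27) # -73
#' @export
percent_change <- function(baseline_mtv, interim_mtv) {
  if (any(!is.finite(baseline_mtv)) || any(!is.finite(interim_mtv)) ||
      any(interim_mtv < 0)) {
    abort("MTV values must be finite and interim >= 0.",
      class = "mtvsurv_invalid_argument")
  }
  if (any(baseline_mtv <= 0)) {
    abort("Relative MTV change is undefined for baseline MTV <= 0.",
      class = "mtvsurv_undefined_change")
  }
  100 * (interim_mtv - baseline_mtv) / baseline_mtv
}

#' Volumetric PR/SD/PD response classification
#'
#' Classifies the relative MTV change after the first two PRRT cycles:
#' partial response (PR) is a reduction of more than 73%, progressive
#' disease (PD) an increase of more than 63%, and stable disease (SD)
#' everything between. "More than" is strict, so the boundary values -73
#' and +63 are SD.
#'
#' @param pct_change Percent MTV change from [percent_change()]. Vectorized.
#' @param pr_threshold Percent change below which the class is PR.
#'   Default -73.
#' @param pd_threshold Percent change above which the class is PD.
#'   Default +63.
#' @return Factor with levels `PR`, `SD`, `PD`.
#' @examples
#' classify_response(c(-74, -73, 0, 63, 64))
#' @export
classify_response <- function(pct_change, pr_threshold = -73, pd_threshold = 63) {
  if (any(!is.finite(pct_change))) {
    abort("`pct_change` must be finite.", class = "mtvsurv_invalid_argument")
  }
  if (!(pr_threshold < 0 && 0 < pd_threshold)) {
    abort("Response thresholds must satisfy PR < 0 < PD.",
      class = "mtvsurv_invalid_argument")
  }
  cls <- ifelse(pct_change < pr_threshold, "PR",
    ifelse(pct_change > pd_threshold, "PD", "SD"))
  factor(cls, levels = c("PR", "SD", "PD"))
}

#' Responder flag
#'
#' PR and SD count as responders; PD defines a non-responder.
#'
#' @param cls Factor or character of `PR`/`SD`/`PD` labels.
#' @return Logical, `TRUE` for responders.
#' @export
is_responder <- function(cls) {
  cls <- as.character(cls)
  if (!all(cls %in% c("PR", "SD", "PD"))) {
    abort("Response classes must be PR, SD or PD.",
      class = "mtvsurv_invalid_argument")
  }
  cls != "PD"
}

#' Assess volumetric response for a cohort table
#'
#' Data-frame-first wrapper: computes the percent MTV change, the PR/SD/PD
#' class and the responder flag for every row and appends them as
#' `pct_change`, `response` and `responder` columns.
#'
#' @param data A data frame with baseline and interim MTV columns.
#' @param baseline,interim Columns holding baseline and interim MTV (ml),
#'   given tidyselect-style. Defaults `mtv_baseline_ml`, `mtv_interim_ml`.
#' @inheritParams classify_response
#' @return `data` as a tibble with the three response columns appended.
#' @examples
#' tibble::tibble(mtv_baseline_ml = c(100, 50), mtv_interim_ml = c(20, 90)) |>
#'   assess_response()
#' @export
assess_response <- function(data, baseline = "mtv_baseline_ml",
                            interim = "mtv_interim_ml",
                            pr_threshold = -73, pd_threshold = 63) {
  b <- dplyr::pull(data, {{ baseline }})
  i <- dplyr::pull(data, {{ interim }})
  pct <- percent_change(b, i)
  as_tibble(data) |>
    dplyr::mutate(
      pct_change = pct,
      response = classify_response(pct, pr_threshold, pd_threshold),
      responder = is_responder(.data$response)
    )
}
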