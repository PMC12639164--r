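# Multivariable logistic baseline on vendor-style morphology measurements.

baseline_design <- function(records) {
  feats <- baseline_features()
  get_col <- function(f) {
    if (!is.null(records[[paste0("tbp_lv_", f)]])) {
      records[[paste0("tbp_lv_", f)]]
    } else if (!is.null(records[[f]])) {
      records[[f]]
    } else {
      stopf("baseline predictor '%s' not found in records", f)
    }
  }
  X <- as.data.frame(lapply(stats::setNames(feats, feats), get_col))
  if (is.null(records$anatom_site_general)) {
    stopf("records must contain anatom_site_general")
  }
  site <- factor(records$anatom_site_general, levels = anatomic_sites())
  if (anyNA(site)) stopf("anatom_site_general contains unknown categories")
  for (s in anatomic_sites()[-1]) {  # head/neck is the reference
    X[[paste0("site_", gsub("[ /]", "_", s))]] <- as.numeric(site == s)
  }
  X
}

#' Fit the multivariable logistic triage baseline
#'
#' Logistic regression of malignancy on exactly eleven morphology
#' measurements ([baseline_features()]) plus the five anatomic-site
#' categories (one-hot, reference = head/neck). Constant (degenerate)
#' predictors are dropped with a warning. Fitted coefficients can be replaced
#' wholesale via `coefficients`, e.g. to evaluate externally published
#' coefficients instead of refitting.
#'
#' @param records Data frame with the eleven measurements (either bare or
#'   `tbp_lv_`-prefixed column names), `anatom_site_general`, and -- unless
#'   `coefficients` is supplied -- a 0/1 `target` column.
#' @param coefficients Optional named numeric vector (names as in the design:
#'   `(Intercept)`, measurement names, `site_*`). Unnamed entries are not
#'   allowed; design columns absent from the vector get coefficient 0.
#' @return Object of class `tbp_baseline` with elements `coefficients` and
#'   `dropped` (names of constant predictors removed during fitting).
#' @export
fit_baseline <- function(records, coefficients = NULL) {
  X <- baseline_design(records)
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
      stopf("coefficients must be a fully named vector")
    }
    obj <- list(coefficients = coefficients, dropped = character(0))
    class(obj) <- "tbp_baseline"
    return(obj)
  }
  if (is.null(records$target)) stopf("records must contain a target column")
  y <- check_binary_labels(records$target)
  keep <- vapply(X, function(col) stats::sd(col) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping constant baseline predictor(s): %s",
                    paste(names(X)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, Xk),
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  cf[!is.finite(cf)] <- 0
  # glm backtick-quotes non-syntactic names; strip for stable matching
  names(cf) <- gsub("`", "", names(cf))
  obj <- list(coefficients = cf, dropped = names(X)[!keep])
  class(obj) <- "tbp_baseline"
  obj
}

#' Predict malignancy scores from the logistic baseline
#'
#' @param object A `tbp_baseline`.
#' @param newdata Records data frame (same column conventions as
#'   [fit_baseline()]).
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.tbp_baseline <- function(object, newdata, ...) {
  X <- baseline_design(newdata)
  eta <- rep(unname(object$coefficients["(Intercept)"] %||% 0), nrow(X))
  eta[is.na(eta)] <- 0
  for (nm in names(X)) {
    b <- object$coefficients[nm]
    if (!is.na(b)) eta <- eta + b * X[[nm]]
  }
  stats::plogis(eta)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
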