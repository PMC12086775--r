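#' Dose design for a parallel-group trial
#'
#' Describes the frame every contrast lives on: an ordered dose grid with the
#' placebo/control dose first, and the number of patients randomized to each
#' arm.
#'
#' @param doses Numeric vector of dose levels, strictly increasing, with the
#'   control (usually 0) first.
#' @param n Positive integer vector of per-arm sample sizes, same length as
#'   `doses`. A single value is recycled to all arms.
#' @return An object of class `"dose_design"` with elements `doses`, `n`,
#'   `k` (number of active doses) and `N` (total sample size).
#' @examples
#' dose_design(c(0, 0.1, 0.4, 1), 100)
#' @export
dose_design <- function(doses, n) {
  doses <- as.numeric(doses)
  if (length(doses) < 2L)
    stop("need a control and at least one active dose")
  if (any(!is.finite(doses)) || any(diff(doses) <= 0))
    stop("'doses' must be finite and strictly increasing (control first)")
  if (length(n) == 1L) n <- rep(n, length(doses))
  n <- as.integer(n)
  if (length(n) != length(doses) || any(is.na(n)) || any(n < 1L))
    stop("'n' must give a positive sample size for every arm")
  structure(
    list(doses = doses, n = n, k = length(doses) - 1L, N = sum(n)),
    class = "dose_design"
  )
}

#' @export
print.dose_design <- function(x, ...) {
  cat("Dose design:", x$k, "active doses + control,", "N =", x$N, "\n")
  print(data.frame(dose = x$doses, n = x$n), row.names = FALSE)
  invisible(x)
}

.model_families <- c("emax", "sigEmax", "betaMod", "exponential", "linear")

#' Candidate dose-response model
#'
#' A standardized dose-response shape with guessed ("design-stage") shape
#' parameters. Standardized shapes are defined only up to an affine
#' transformation; [scaled_profile()] anchors them to a placebo effect of 0
#' and a chosen maximum effect.
#'
#' Supported families and their shape parameters:
#' \describe{
#'   \item{emax}{`ed50 > 0`; shape `d / (ed50 + d)`.}
#'   \item{sigEmax}{`ed50 > 0`, Hill exponent `h > 0`; shape
#'     `d^h / (ed50^h + d^h)`.}
#'   \item{betaMod}{`delta1, delta2 > 0` and `scale` strictly larger than the
#'     maximum dose; shape `(d/scale)^delta1 * (1 - d/scale)^delta2` (the
#'     beta-function normalizing constant is dropped; it is absorbed by the
#'     affine scaling).}
#'   \item{exponential}{`rate > 0`; shape `exp(d/rate) - 1`.}
#'   \item{linear}{no parameters; shape `d`.}
#' }
#'
#' @param family One of `"emax"`, `"sigEmax"`, `"betaMod"`, `"exponential"`,
#'   `"linear"`.
#' @param ... Family-specific shape parameters, see Details.
#' @param label Optional model label used in tables and reports.
#' @return An object of class `"candidate_model"`.
#' @examples
#' candidate_model("emax", ed50 = 0.05, label = "Emax1")
#' candidate_model("sigEmax", ed50 = 0.6, h = 2)
#' @export
candidate_model <- function(family, ..., label = NULL) {
  family <- match.arg(family, .model_families)
  params <- list(...)
  need <- switch(family,
    emax = "ed50",
    sigEmax = c("ed50", "h"),
    betaMod = c("delta1", "delta2", "scale"),
    exponential = "rate",
    linear = character(0)
  )
  if (!setequal(names(params), need))
    stop(sprintf("family '%s' needs parameter(s): %s", family,
                 if (length(need)) paste(need, collapse = ", ") else "none"))
  params <- lapply(params[need], as.numeric)
  if (any(vapply(params, function(p) !is.finite(p) || p <= 0, logical(1))))
    stop("all shape parameters must be finite and strictly positive")
  if (is.null(label))
    label <- if (length(params))
      paste0(family, "(", paste(unlist(params), collapse = ", "), ")")
    else family
  structure(list(family = family, params = params, label = label),
            class = "candidate_model")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(x$label, ": ", x$family, sep = "")
  if (length(x$params))
    cat(" [", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Candidate model set
#'
#' @param ... `candidate_model` objects (or a single list of them). Names, if
#'   given, override the model labels.
#' @return An object of class `"candidate_set"`: a labelled list of models.
#' @seealso [default_candidate_set()]
#' @export
candidate_set <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1L]]) &&
      !inherits(models[[1L]], "candidate_model"))
    models <- models[[1L]]
  if (!length(models)) stop("need at least one candidate model")
  if (!all(vapply(models, inherits, logical(1), "candidate_model")))
    stop("all elements must be candidate_model objects")
  nm <- names(models)
  for (i in seq_along(models))
    if (!is.null(nm) && nzchar(nm[i])) models[[i]]$label <- nm[i]
  labels <- vapply(models, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("model labels must be unique")
  names(models) <- labels
  structure(models, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set of", length(x), "dose-response shapes:\n")
  for (m in x) print(m)
  invisible(x)
}

#' Default candidate set of five monotone shapes
#'
#' Three Emax shapes (ED50 = 0.05, 0.2, 0.7) and two sigmoid Emax shapes
#' (h = 3 with ED50 = 0.25; h = 2 with ED50 = 0.6), suitable for a dose range
#' rescaled to a maximum dose of 1. This is the candidate set used throughout
#' the package's worked examples.
#'
#' @return A [candidate_set()] with models `Emax1`, `Emax2`, `Emax3`,
#'   `sigEmax1`, `sigEmax2`.
#' @export
default_candidate_set <- function() {
  candidate_set(
    Emax1 = candidate_model("emax", ed50 = 0.05),
    Emax2 = candidate_model("emax", ed50 = 0.2),
    Emax3 = candidate_model("emax", ed50 = 0.7),
    sigEmax1 = candidate_model("sigEmax", ed50 = 0.25, h = 3),
    sigEmax2 = candidate_model("sigEmax", ed50 = 0.6, h = 2)
  )
}

#' Standardized model response
#'
#' Evaluates the standardized shape of a candidate model at one or more
#' doses. All supported shapes are 0 at dose 0 and are defined only up to the
#' affine transformation applied by [scaled_profile()].
#'
#' @param model A [candidate_model()].
#' @param dose Nonnegative numeric vector of doses; for `betaMod` doses must
#'   not exceed the `scale` parameter.
#' @return Numeric vector of standardized responses.
#' @examples
#' std_response(candidate_model("emax", ed50 = 0.2), c(0, 0.2, 1))
#' @export
std_response <- function(model, dose) {
  stopifnot(inherits(model, "candidate_model"))
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and nonnegative")
  p <- model$params
  switch(model$family,
    emax = dose / (p$ed50 + dose),
    sigEmax = dose^p$h / (p$ed50^p$h + dose^p$h),
    betaMod = {
      if (any(dose > p$scale))
        stop("betaMod: dose exceeds the scale parameter")
      (dose / p$scale)^p$delta1 * (1 - dose / p$scale)^p$delta2
    },
    exponential = expm1(dose / p$rate),
    linear = dose
  )
}

.profile_degenerate <- function(f) {
  rng <- max(f) - min(f)
  rng <= 1e-12 * max(1, max(abs(f)))
}

#' Placebo-anchored mean profile
#'
#' Applies the affine transformation that maps a standardized shape to a mean
#' vector with effect 0 at placebo and a given maximum effect at the design
#' dose where the shape attains its maximum.
#'
#' @param model A [candidate_model()].
#' @param design A [dose_design()].
#' @param effect Targeted maximum effect (response units). The returned
#'   profile has value 0 at the control dose and maximum `effect` (for
#'   `effect > 0`).
#' @return Numeric vector of arm means aligned to `design$doses`.
#' @examples
#' d <- dose_design(c(0, 0.1, 0.4, 1), 100)
#' scaled_profile(candidate_model("emax", ed50 = 0.2), d, effect = 0.5)
#' @export
scaled_profile <- function(model, design, effect) {
  stopifnot(inherits(design, "dose_design"), is.finite(effect))
  f <- std_response(model, design$doses)
  f <- f - f[1L]
  if (.profile_degenerate(f))
    stop("standardized shape is constant over the design doses")
  effect * f / max(f)
}

#' Dose of maximum efficacy within a design
#'
#' @param model A [candidate_model()].
#' @param design A [dose_design()].
#' @return The design dose at which the standardized shape is largest; ties
#'   are broken toward the smallest such dose.
#' @export
max_effect_dose <- function(model, design) {
  stopifnot(inherits(design, "dose_design"))
  f <- std_response(model, design$doses)
  if (.profile_degenerate(f - f[1L]))
    stop("standardized shape is constant over the design doses")
  design$doses[which.max(f)]
}
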