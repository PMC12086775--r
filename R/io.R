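# Formats and configuration: delimited trial data, YAML/JSON run configs,
# report serialization, and a deterministic example-trial generator.

#' Read per-patient trial data from a delimited file
#'
#' Expects a header with columns `dose` and `response` (and optionally
#' `endpoint`). Dose values must match the design grid exactly after
#' numeric parsing; a tolerance-based match is deliberately not offered,
#' since silent mis-binning is worse than a hard error.
#'
#' @param path CSV file path.
#' @param design A [dose_design()] to validate doses against.
#' @return A data frame (`dose`, `response`); if an `endpoint` column with
#'   several levels is present, a named list of such data frames, one per
#'   endpoint.
#' @export
read_trial_csv <- function(path, design) {
  stopifnot(inherits(design, "dose_design"))
  dat <- utils::read.csv(path, header = TRUE)
  if (!nrow(dat)) stop("empty trial data file: ", path)
  if (!all(c("dose", "response") %in% names(dat)))
    stop("trial data needs columns 'dose' and 'response'")
  dat$dose <- as.numeric(dat$dose)
  dat$response <- as.numeric(dat$response)
  bad <- which(is.na(match(dat$dose, design$doses)))
  if (length(bad))
    stop("dose values not in the design grid at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), ": ",
         paste(unique(dat$dose[bad]), collapse = ", "))
  if ("endpoint" %in% names(dat)) {
    eps <- unique(dat$endpoint)
    if (length(eps) > 1L)
      return(lapply(stats::setNames(eps, eps), function(e)
        dat[dat$endpoint == e, c("dose", "response")]))
  }
  dat[c("dose", "response")]
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognized keys: `design` (with `doses`, `n`), `models` (list of
#' `{label, family, params}`), `alpha`, `constrained`, `seed`. Unknown keys
#' are rejected.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return List with `design` ([dose_design()]), `models`
#'   ([candidate_set()]), `alpha`, `constrained`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("design", "models", "alpha", "constrained", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  # accept "allocation" or "n" for the per-arm sample sizes; an unquoted
  # bare "n" key is a YAML 1.1 boolean, which yaml::read_yaml renders "FALSE"
  alloc <- cfg$design$allocation
  if (is.null(alloc)) alloc <- cfg$design$n
  if (is.null(alloc)) alloc <- cfg$design[["FALSE"]]
  if (is.null(cfg$design$doses) || is.null(alloc))
    stop("config must provide design: {doses, allocation}")
  design <- dose_design(unlist(cfg$design$doses), unlist(alloc))
  if (is.null(cfg$models)) stop("config must provide a candidate model list")
  models <- candidate_set(lapply(cfg$models, function(m) {
    do.call(candidate_model,
            c(list(family = m$family, label = m$label), as.list(m$params)))
  }))
  list(design = design, models = models,
       alpha = if (is.null(cfg$alpha)) 0.025 else as.numeric(cfg$alpha),
       constrained = if (is.null(cfg$constrained)) TRUE
                     else isTRUE(cfg$constrained),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Write a closed-test report
#'
#' @param report A `"closed_mcpmod"` object.
#' @param path Output file path.
#' @param format One of `"json"`, `"csv"`, `"text"`. JSON round-trips the
#'   numeric content; CSV holds the per-intersection table with the
#'   elementary results appended; text mirrors the printed report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  stopifnot(inherits(report, "closed_mcpmod"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(
      alpha = report$alpha,
      constrained = report$constrained,
      global_p = report$global_p,
      intersections = report$intersection_table,
      elementary = report$elementary
    ), path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  } else if (format == "csv") {
    itab <- report$intersection_table
    utils::write.csv(itab, path, row.names = FALSE)
    el <- report$elementary
    names(el)[names(el) == "adjusted_p"] <- "p_value"
    suppressWarnings(utils::write.table(
      el[c("hypothesis", "p_value", "reject")], path, sep = ",",
      row.names = FALSE, col.names = FALSE, append = TRUE))
  } else {
    out <- utils::capture.output(print(report))
    writeLines(out, path)
  }
  invisible(path)
}

#' Re-read a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return List with the report's numeric content (`alpha`, `constrained`,
#'   `global_p`, `intersections`, `elementary` data frames).
#' @export
read_report_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$intersections <- as.data.frame(rep$intersections)
  rep$elementary <- as.data.frame(rep$elementary)
  rep
}

#' Deterministic example-trial bundle
#'
#' Simulates one trial on the four-arm case-study design (doses 0, 0.1,
#' 0.4, 1; 100 patients per arm; residual SD 1; Emax ED50 = 0.2 truth with
#' maximum effect 0.4) and analyzes it with the closed contrast-test
#' procedure under both contrast variants. Fixed seed, so the bundle is
#' identical on every call.
#'
#' @param seed Master seed.
#' @return List with `data`, `design`, `models`, and reports
#'   `constrained` / `unconstrained` (unconstrained-variant warning
#'   suppressed in the bundle).
#' @export
make_fixture <- function(seed = 1L) {
  design <- dose_design(c(0, 0.1, 0.4, 1), 100L)
  models <- default_candidate_set()
  scen <- scenario(design, candidate_model("emax", ed50 = 0.2), effect = 0.4,
                   sigma = 1, nsim = 1L, seed = seed)
  data <- simulate_trial(scen, replicate = 1L)
  list(
    data = data,
    design = design,
    models = models,
    constrained = closed_mcpmod(data, design, models, constrained = TRUE),
    unconstrained = suppressWarnings(
      closed_mcpmod(data, design, models, constrained = FALSE))
  )
}
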