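# Flat-file interfaces: sweep and epi series as CSV, fit results as JSON,
# run metadata alongside every CLI output.

#' Write / read a dose sweep as CSV
#'
#' Column order is fixed (`mu1,mean_dose,events,trials,rate`); values
#' round-trip exactly (full double precision on write).
#'
#' @param sweep A [run_sweep()] result or compatible data frame.
#' @param path File path.
#' @return `read_sweep_csv` returns a `dose_sweep` data frame;
#'   `write_sweep_csv` returns `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  sweep <- as.data.frame(sweep)
  cols <- c("mu1", "mean_dose", "events", "trials", "rate")
  stopifnot(all(cols %in% names(sweep)))
  out <- sweep[cols]
  # full precision so that rate * trials == events survives the round trip
  for (col in c("mu1", "mean_dose", "rate"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  out <- utils::read.csv(path, colClasses = c(
    mu1 = "numeric", mean_dose = "numeric", events = "integer",
    trials = "numeric", rate = "numeric"))
  if (any(abs(out$rate * out$trials - out$events) > 1e-6))
    stop(sprintf("corrupt sweep file %s: rate * trials != events", path))
  class(out) <- c("dose_sweep", "data.frame")
  out
}

#' Write / read an epidemiological series as CSV
#'
#' Header `period,births,deaths,burden`.
#'
#' @param records An `epi_series` data frame.
#' @param path File path.
#' @export
write_epi_csv <- function(records, path) {
  records <- as.data.frame(records)
  cols <- c("period", "births", "deaths", "burden")
  stopifnot(all(cols %in% names(records)))
  out <- records[cols]
  out$burden <- sprintf("%.17g", out$burden)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_epi_csv
#' @export
read_epi_csv <- function(path) {
  out <- utils::read.csv(path, colClasses = c(
    period = "integer", births = "integer", deaths = "integer",
    burden = "numeric"))
  if (any(out$deaths > out$births)) stop("deaths exceed births")
  if (any(out$burden < 0)) stop("negative burden")
  class(out) <- c("epi_series", "data.frame")
  out
}

fit_to_list <- function(fit) {
  if (inherits(fit, "dose_response_fit"))
    return(list(model = fit$model, estimates = as.list(fit$estimates),
                std_errors = as.list(fit$std_errors),
                deviance = fit$deviance, df = fit$df,
                converged = fit$converged, n_iterations = fit$n_iterations))
  if (inherits(fit, "epi_fit"))
    return(list(model = "epi_lagged_lognormal_excess",
                baseline_coefficients = as.list(fit$baseline_coefficients),
                amplitude = fit$amplitude, mu = fit$mu, sigma = fit$sigma,
                std_errors = as.list(fit$std_errors),
                deviance = fit$deviance, df = fit$df,
                reduced_deviance = fit$reduced$deviance,
                reduced_df = fit$reduced$df,
                p_cesium = fit$p_cesium, lag = fit$spec$lag,
                converged = fit$converged))
  stop("unsupported fit object")
}

#' Serialize a fit result to JSON
#'
#' @param fit A `dose_response_fit` or `epi_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

write_run_metadata <- function(path, command, config) {
  meta <- list(command = command, config = config,
               package = "teratodose",
               version = as.character(utils::packageVersion("teratodose")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
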