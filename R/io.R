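#' Write a trajectory as TSV
#'
#' Tab-separated, header \code{time m0 m1 m2 c cstar [cm0 cstarm1]}, full
#' double precision (\code{\%.12g}); byte-deterministic for fixed input.
#'
#' @param traj a \code{ccc_trajectory} (any data.frame works).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(x) sprintf("%.12g", x)),
                             sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory TSV
#'
#' @param path file written by \code{\link{write_trajectory}}.
#' @return data.frame of class \code{ccc_trajectory}.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  structure(df, class = c("ccc_trajectory", "data.frame"))
}

#' Write a key/value report as JSON
#'
#' Keys are sorted so repeated runs diff cleanly; numbers keep full
#' precision.
#'
#' @param mapping named list of scalars (or small vectors).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(mapping, path) {
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("report entries must be named")
  mapping <- mapping[order(names(mapping))]
  jsonlite::write_json(mapping, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

ccc_config_defaults <- function() {
  c(unclass(ccc_params()),
    list(m0 = 0, m1 = 0, m2 = 0, c = 2, cstar = 0, cm0 = 0, cstarm1 = 0,
         model = "reduced5", t_end = 100, sample_dt = 1))
}

#' Load and validate a simulation configuration
#'
#' A flat JSON object naming any subset of the parameter fields (kin, kleak,
#' kout, kc, kp, K0, K1, ka0, ka1), initial-state fields (m0, m1, m2, c,
#' cstar, cm0, cstarm1), and run settings (model, t_end, sample_dt).
#' Missing keys take the package defaults; unknown keys are rejected by
#' name.
#'
#' @param path a JSON file, or a named list already in memory.
#' @return List with validated components \code{params}
#'   (\code{\link{ccc_params}}), \code{state0} (\code{\link{ccc_state}}),
#'   \code{model}, \code{t_end}, \code{sample_dt}, and \code{raw} (the
#'   merged flat list).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else path
  if (!is.list(cfg)) stop("configuration must be a JSON object")
  defaults <- ccc_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, cfg)
  for (k in setdiff(names(merged), "model"))
    if (!is.numeric(merged[[k]]) || length(merged[[k]]) != 1)
      stop("configuration key '", k, "' must be a single number")
  if (!merged$model %in% c("full", "reduced5", "reduced2"))
    stop("model must be one of full, reduced5, reduced2")
  if (merged$t_end <= 0 || merged$sample_dt <= 0)
    stop("t_end and sample_dt must be positive")
  params <- do.call(ccc_params, merged[names(unclass(ccc_params()))])
  state0 <- do.call(ccc_state,
                    merged[c("m0", "m1", "m2", "c", "cstar", "cm0", "cstarm1")])
  list(params = params, state0 = state0, model = merged$model,
       t_end = merged$t_end, sample_dt = merged$sample_dt, raw = merged)
}

#' Serialise a configuration back to flat JSON
#'
#' @param config the list returned by \code{\link{load_config}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
dump_config <- function(config, path) {
  write_report(config$raw, path)
}
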