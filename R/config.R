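#' Read and write flat run configurations
#'
#' A run configuration is a flat named list of scalars (YAML on disk) with
#' keys from `n, kappa1, kappa2, kappa3, kappa_m1, kappa_m, p0, q0, r0,
#' t_end, rtol, atol, seed, replicates, k0`. `read_run_config()` validates
#' key names and scalar-ness; unknown keys are an error so that typos
#' surface before any computation.
#'
#' @param path File path.
#' @param config Named list of scalars.
#' @return `read_run_config()` returns the named list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # an unquoted `n:` key is a YAML 1.1 boolean; map it back
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

run_config_keys <- c("n", "kappa1", "kappa2", "kappa3", "kappa_m1",
                     "kappa_m", "p0", "q0", "r0", "t_end", "rtol", "atol",
                     "seed", "replicates", "k0")

validate_run_config <- function(cfg) {
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("config must be a named list", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(cfg)[!vapply(cfg, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1L))]
  if (length(bad) > 0) {
    stop("config values must be finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build model inputs from a run configuration
#'
#' Splits a validated flat configuration into a [rate_constants()] object,
#' an initial continuum state and the numerical settings.
#'
#' @param cfg Named list as returned by [read_run_config()].
#' @return A list with elements `params`, `init`, `settings`.
#' @export
config_to_inputs <- function(cfg) {
  validate_run_config(cfg)
  need <- c("n", "kappa1", "kappa2", "kappa3", "kappa_m1", "kappa_m")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    stop("missing config keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  params <- rate_constants(cfg$n, cfg$kappa1, cfg$kappa2, cfg$kappa3,
                           cfg$kappa_m1, cfg$kappa_m,
                           k0 = cfg$k0)
  init <- NULL
  if (all(c("p0", "q0", "r0") %in% names(cfg))) {
    init <- c(p = cfg$p0, q = cfg$q0, r = cfg$r0)
  }
  settings <- cfg[intersect(c("t_end", "rtol", "atol", "seed",
                              "replicates", "k0"), names(cfg))]
  list(params = params, init = init, settings = settings)
}

#' JSON regime report
#'
#' Serialises a [classify_regime()] result as UTF-8 JSON with keys
#' `alpha_bar, q_hat, regime, boundary, steady_state, asymptotics`.
#'
#' @param report A `regime_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "regime_report"))
  obj <- list(
    alpha_bar = report$alpha_bar,
    q_hat = report$q_hat,
    regime = report$regime,
    boundary = report$boundary,
    steady_state = if (is.null(report$steady_state)) NULL else
      as.list(report$steady_state),
    asymptotics = if (is.null(report$asymptotics)) NULL else
      as.list(report$asymptotics[c("p1", "q2", "r2")])
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}
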