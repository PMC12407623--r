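#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnbinom rnorm rlnorm var pnorm phyper setNames
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "metascore_error")))
}

config_error <- function(msg) abort(msg, "metascore_config_error")
format_error <- function(msg) abort(msg, "metascore_format_error")
data_error   <- function(msg) abort(msg, "metascore_data_error")

#' Evaluate code with a private, restored RNG state
#'
#' All stochastic steps (control-gene draws, Louvain sweep order, simulation)
#' run inside a seeded scope so results are reproducible and the caller's RNG
#' stream is untouched.
#' @noRd
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# scalar validators used by the config constructors
check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    config_error(sprintf("'%s' must be a single fraction in %s, got %s",
                         name, if (open) "(0,1)" else "[0,1]",
                         paste(format(x), collapse = ",")))
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x) && x >= min
  if (!ok) {
    config_error(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!ok) config_error(sprintf("'%s' must be a single positive number", name))
  as.numeric(x)
}
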