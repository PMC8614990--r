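#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed and a key
#'
#' All stochastic entry points in the package accept a single integer seed;
#' independent substreams (e.g. one per grid point of a sensitivity curve)
#' are derived deterministically from the master seed plus a string key, so
#' that results are reproducible and substreams do not overlap by
#' construction of the RNG state.
#'
#' @param seed master integer seed.
#' @param ... key components (coerced to character) identifying the
#'   substream, e.g. a parameter name and a grid index.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

stop_config <- function(...) {
  stop(structure(class = c("ipm_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_domain <- function(...) {
  stop(structure(class = c("ipm_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("ipm_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_config(msg)
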