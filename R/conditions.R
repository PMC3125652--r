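# Classed conditions used across the package. Every user-facing failure is
# raised as one of these so callers (and tests) can distinguish bad input
# values (domain), corrupt records (data), bad configuration, and I/O.

bm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "bm_error"), call = call))
}

bm_domain_error <- function(msg) bm_stop(msg, "bm_domain_error")
bm_data_error <- function(msg) bm_stop(msg, "bm_data_error")
bm_config_error <- function(msg) bm_stop(msg, "bm_config_error")
bm_capacity_error <- function(msg) bm_stop(msg, "bm_capacity_error")
bm_io_error <- function(msg) bm_stop(msg, "bm_io_error")

stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    bad <- if (is.numeric(x)) which(!is.finite(x) | x <= 0) else integer()
    bm_domain_error(sprintf(
      "'%s' must be strictly positive and finite%s", what,
      if (length(bad)) sprintf(" (offending index: %s)",
                               paste(utils::head(bad, 5L), collapse = ", "))
      else ""))
  }
  invisible(x)
}
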