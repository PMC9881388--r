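#' @keywords internal
"_PACKAGE"

## Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Names of the 12 arm-position-matching parameters
#'
#' Trial-to-trial variability, contraction/expansion ratio, systematic
#' spatial shift and absolute error, each resolved in the x, y and
#' combined xy directions.
#'
#' @return Character vector of length 12.
#' @export
apm_parameter_names <- function() {
  c("var_x", "var_y", "var_xy",
    "ce_x", "ce_y", "ce_xy",
    "shift_x", "shift_y", "shift_xy",
    "ae_x", "ae_y", "ae_xy")
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

## c4 correction: E[sample SD]/sigma for a normal sample of size n
c4_factor <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}
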