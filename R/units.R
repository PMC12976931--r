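#' Parse a concentration with an optional unit suffix
#'
#' Configuration files state concentrations as numbers (already molar) or as
#' strings with a metric suffix: `"M"`, `"mM"`, `"uM"` (or `"µM"`),
#' `"nM"`, `"pM"`. All values are converted to molar.
#'
#' @param x Numeric (returned as-is) or character scalar/vector like
#'   `"5uM"`, `"530 nM"`.
#' @return Numeric concentration(s) in molar.
#' @examples
#' parse_conc("5uM")     # 5e-6
#' parse_conc("530 nM")  # 5.3e-7
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x)) stop("concentration must be numeric (molar) or a unit string")
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)
  out <- vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(M|mM|uM|µM|nM|pM)$", s))[[1]]
    if (length(m) != 3L)
      stop(sprintf("cannot parse concentration '%s' (expected e.g. '5uM', '1e-6M')", s))
    as.numeric(m[2]) * scale[[m[3]]]
  }, 0, USE.NAMES = FALSE)
  out
}

#' Logarithmically spaced grid
#'
#' `n` points spaced evenly in log10 between `from` and `to`; the default
#' axis type for effector concentrations and dissociation constants.
#'
#' @param from,to Positive endpoints.
#' @param n Number of points.
#' @return Numeric vector of length `n`.
#' @export
log_grid <- function(from, to, n) 10^seq(log10(from), log10(to), length.out = n)

# scalar finite non-negative check
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be finite and >= 0", name))
  invisible(x)
}
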