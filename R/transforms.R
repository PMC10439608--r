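TRANSFORM_METHODS <- c("none", "square", "cube", "sqrt", "cbrt", "log", "exp",
                       "logit", "arcsine", "rank")

#' Transform a numeric vector for display, histogramming or distances
#'
#' Element-wise transforms for skewed or bounded biological quantities
#' (coverage depths, GC fractions, proportions). Out-of-domain inputs
#' (e.g. `log` of a zero-coverage contig, `logit` outside (0,1)) map to
#' missing rather than raising, so toggling transforms over exploratory
#' data never aborts; the count of such values is attached as a report.
#'
#' Methods: `square` x^2; `cube` x^3; `sqrt` (x >= 0); `cbrt`
#' sign-preserving cube root; `log` base-10 (x > 0); `exp` 10^x (the
#' inverse of `log`); `logit` ln(x/(1-x)) on (0,1); `arcsine`
#' asin(sqrt(x)) on \[0,1\]; `rank` 1-based ranks with ties averaged
#' (missing values keep no rank).
#'
#' @param values Numeric vector, possibly with `NA`.
#' @param method One of the methods above (or `"none"`).
#' @return Numeric vector of the same length; `attr(, "domain_report")`
#'   gives `n_out_of_domain`.
#' @export
#' @examples
#' transform_values(c(1, 10, 100), "log")
#' transform_values(c(10, 20, 20, 30), "rank")
transform_values <- function(values, method = "none") {
  method <- match.arg(method, TRANSFORM_METHODS)
  x <- as.numeric(values)
  n_missing_in <- sum(is.na(x))
  out <- suppressWarnings(switch(method,
    none = x,
    square = x^2,
    cube = x^3,
    sqrt = ifelse(x >= 0, sqrt(pmax(x, 0)), NA_real_),
    cbrt = sign(x) * abs(x)^(1 / 3),
    log = ifelse(x > 0, log10(x), NA_real_),
    exp = 10^x,
    logit = ifelse(x > 0 & x < 1, log(x / (1 - x)), NA_real_),
    arcsine = ifelse(x >= 0 & x <= 1, asin(sqrt(pmin(pmax(x, 0), 1))), NA_real_),
    rank = {
      r <- rep(NA_real_, length(x))
      ok <- !is.na(x)
      r[ok] <- rank(x[ok], ties.method = "average")
      r
    }
  ))
  out[!is.finite(out)] <- NA_real_
  attr(out, "domain_report") <- list(n_out_of_domain = sum(is.na(out)) - n_missing_in)
  out
}
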