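#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats rbinom rnbinom rnorm runif rbeta rlnorm plogis qlogis
#'   quantile median sd var t.test ks.test pnorm qnorm coef optim setNames
#'   lm.wfit approx
#' @importFrom utils write.table read.table head
NULL

# Stop with a classed condition so callers can test for configuration errors
# specifically rather than matching message text.
stop_config <- function(msg, field = NULL) {
  stop(structure(
    class = c("pmt_config_error", "error", "condition"),
    list(message = if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field),
         call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(sprintf("'%s' must be a single finite number", name), name)
  if (integerish && x != round(x))
    stop_config(sprintf("'%s' must be an integer", name), name)
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper)
    stop_config(sprintf("'%s' must be in %s%g, %g]", name,
                        if (strict_lower) "(" else "[", lower, upper), name)
  invisible(x)
}

#' Weighted quantile (interpolated)
#'
#' Quantile of `x` under nonnegative weights `w`, linearly interpolating the
#' weighted empirical CDF evaluated at the sorted data points.  With equal
#' weights this reduces to `stats::quantile(type = 4)`-like interpolation;
#' only the ordering behaviour matters for knot placement.
#'
#' @param x numeric vector.
#' @param w nonnegative weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    stats::approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministic integer hash of `(global_seed, label)` so that adding a
#' pipeline stage never perturbs another stage's random stream.  Result is a
#' positive integer below 2^31.
#'
#' @param global_seed integer.
#' @param label character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, label) {
  check_scalar_number(global_seed, "global_seed", integerish = TRUE)
  h <- as.double(global_seed %% 2147483647)
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h %% 2147483587 + 1)
}

# Trapezoidal rule on an evenly spaced grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
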