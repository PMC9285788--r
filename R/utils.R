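# internal helpers shared across modules

# classed condition for "profile skipped" failures so the pipeline can
# distinguish a skippable precondition violation from a programming error
stop_skip <- function(...) {
  stop(structure(
    class = c("phytopart_skip", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# trapezoid integral of y over x (x increasing)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# central-difference gradient (forward/backward at the ends), numpy-style
grad1 <- function(y) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1] <- y[2] - y[1]
  g[n] <- y[n] - y[n - 1]
  if (n > 2L) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  g
}

#' Column integral by the trapezoid method
#'
#' Trapezoid integral of a depth-resolved quantity from the shallowest
#' sample down to `z_limit`, with linear interpolation of the integrand at
#' `z_limit` when it falls between samples.
#'
#' @param values per-depth values
#' @param depth depth, m, strictly increasing
#' @param z_limit lower bound of integration, m; must lie within the sampled
#'   range (at or below the shallowest sample, at or above the deepest)
#' @return column integral, in `values` units times metres
#' @export
integrate_column <- function(values, depth, z_limit) {
  ok <- is.finite(values) & is.finite(depth)
  values <- values[ok]; depth <- depth[ok]
  if (length(depth) < 2L) stop("integrate_column: need at least 2 samples")
  if (any(diff(depth) <= 0)) stop("integrate_column: depth must be increasing")
  if (z_limit < min(depth)) {
    stop("integrate_column: z_limit is above the shallowest sample")
  }
  if (z_limit > max(depth)) {
    stop("integrate_column: z_limit is below the deepest sample")
  }
  keep <- depth <= z_limit
  x <- depth[keep]; y <- values[keep]
  if (max(x) < z_limit) {
    y_end <- stats::approx(depth, values, z_limit)$y
    x <- c(x, z_limit); y <- c(y, y_end)
  }
  trapz(x, y)
}
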