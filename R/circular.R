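#' Circular statistics for SO-spindle phases
#'
#' Small self-contained toolbox for angles in radians. All functions wrap
#' results to (-pi, pi]; degrees helpers are provided because preferred
#' phases are conventionally reported in degrees (0 = SO up-state peak,
#' +/-180 = down-state trough).
#'
#' @param x angle(s) in radians.
#' @name circular
NULL

#' @rdname circular
#' @export
wrap_phase <- function(x) Arg(exp(1i * x))

#' @rdname circular
#' @export
deg <- function(x) x * 180 / pi

#' @rdname circular
#' @export
rad <- function(x) x * pi / 180

#' Circular distance
#'
#' Signed angular difference `a - b`, wrapped to (-pi, pi].
#'
#' @param a,b angles in radians.
#' @return angles in radians in (-pi, pi].
#' @export
circ_dist <- function(a, b) Arg(exp(1i * a) / exp(1i * b))

#' Circular mean and resultant length
#'
#' Mean direction is the angle of the (optionally weighted) mean unit
#' vector; `r` is its length in [0, 1]. With antipodal inputs the resultant
#' length is ~0 and the mean direction is not meaningful; `degenerate` flags
#' this case (r below `tol`).
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @param tol resultant length below which the mean is flagged degenerate.
#' @return list with `mean` (radians in (-pi, pi]), `r`, `n`, `degenerate`.
#' @export
circ_mean <- function(x, w = NULL, tol = 1e-8) {
  if (length(x) == 0L) stop("circ_mean: empty phase vector")
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x) || any(w < 0))
    stop("circ_mean: weights must be non-negative and match x")
  v <- sum(w * exp(1i * x)) / sum(w)
  list(mean = Arg(v), r = Mod(v), n = length(x), degenerate = Mod(v) < tol)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that phases are uniformly distributed on the
#' circle. The statistic is z = n * R^2 where R is the mean resultant
#' length; the p-value uses the standard small-sample series approximation
#' (Zar), accurate for n >= 10 and conservative below.
#'
#' @param x angles in radians, length >= 2.
#' @return list with `z`, `p`, `r`, `n`.
#' @export
rayleigh_test <- function(x) {
  n <- length(x)
  if (n < 2L) stop("rayleigh_test: need at least 2 phases")
  r <- Mod(mean(exp(1i * x)))
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  list(z = z, p = min(max(p, 0), 1), r = r, n = n)
}

#' V test against a hypothesized mean direction
#'
#' Modified Rayleigh test with an a priori reference direction: sensitive
#' to concentration around `ref` specifically. v = n * R * cos(mean - ref);
#' under the null, u = v * sqrt(2/n) is approximately standard normal and
#' the p-value is the upper tail.
#'
#' @param x angles in radians, length >= 2.
#' @param ref reference direction in radians.
#' @return list with `v`, `u`, `p`, `n`, `ref`.
#' @export
v_test <- function(x, ref = 0) {
  n <- length(x)
  if (n < 2L) stop("v_test: need at least 2 phases")
  cm <- circ_mean(x)
  v <- n * cm$r * cos(circ_dist(cm$mean, ref))
  u <- v * sqrt(2 / n)
  list(v = v, u = u, p = stats::pnorm(u, lower.tail = FALSE), n = n, ref = ref)
}

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 falls
# back to uniform. Used by the simulator to jitter spindle centers around
# the injected coupling phase.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(wrap_phase(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- wrap_phase(mu + sign(u3 - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}
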