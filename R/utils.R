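# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# angle between two unit vectors, degrees
.angle_deg <- function(a, b) 180 / pi * acos(.clamp(sum(a * b)))

# antipodally symmetrized angle between axes, degrees; vectorised over rows
.axis_angle_deg <- function(a, b) 180 / pi * acos(.clamp(abs(sum(a * b))))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# unit-normalize rows of a matrix
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) .stopf("zero-length direction vector")
  m / nrm
}

# canonical hemisphere representative of an axis: z > 0, tie-break at z = 0 by
# x > 0 then y > 0 (directions are axes: d and -d are the same measurement)
.canonical_axis <- function(d, tol = 1e-9) {
  if (d[3] < -tol) return(-d)
  if (abs(d[3]) <= tol) {
    if (d[1] < -tol) return(-d)
    if (abs(d[1]) <= tol && d[2] < 0) return(-d)
  }
  d
}
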