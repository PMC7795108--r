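# Internal planar geometry helpers. All coordinates are planar meters.

# Euclidean distance between two points (length-2 numeric vectors).
.dist2 <- function(a, b) sqrt(sum((a - b)^2))

# Project point p onto segment a-b. Returns list(t, point, dist) where t is
# the clamped parameter in [0,1] along a->b.
.project_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else sum((p - a) * ab) / len2
  t <- min(max(t, 0), 1)
  q <- a + t * ab
  list(t = t, point = q, dist = .dist2(p, q))
}

# Proper/touching intersection of segments p1-p2 and q1-q2. Returns the
# intersection point (length-2 numeric) or NULL. Collinear overlaps return
# NULL: the generator never emits them and endpoint-shared segments already
# meet at a common node.
.segment_intersection <- function(p1, p2, q1, q2, tol = 1e-9) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < tol) return(NULL)
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(NULL)
  p1 + min(max(t, 0), 1) * r
}

# Stable key for coordinate de-duplication (sub-millimeter rounding).
.coord_key <- function(xy) {
  paste(round(xy[, 1], 3), round(xy[, 2], 3), sep = "_")
}
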