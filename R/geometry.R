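#' Fold line (polyline) constructor
#'
#' A fold is represented as an ordered 2D polyline in micrometres, either an
#' open segment chain or a closed ring. Side calls for clones and tracks are
#' made against this line.
#'
#' @param vertices two-column numeric matrix (x, y) in um, >= 2 rows.
#' @param closed logical; `TRUE` for a ring (last vertex joins the first).
#' @return an object of class `fold_line`.
#' @export
fold_line <- function(vertices, closed = FALSE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 2L)
    stopf("fold_line needs a numeric matrix with 2 columns and >= 2 rows")
  if (any(!is.finite(vertices))) stopf("fold_line vertices must be finite")
  if (polyline_self_intersects(vertices, closed))
    stopf("fold_line polyline must not self-intersect")
  structure(list(vertices = unname(vertices), closed = isTRUE(closed)),
            class = "fold_line")
}

#' @export
print.fold_line <- function(x, ...) {
  cat(sprintf("<fold_line: %d vertices, %s>\n", nrow(x$vertices),
              if (x$closed) "closed ring" else "open"))
  invisible(x)
}

fold_segments <- function(fold) {
  v <- fold$vertices
  if (fold$closed) v <- rbind(v, v[1L, ])
  list(a = v[-nrow(v), , drop = FALSE], b = v[-1L, , drop = FALSE])
}

# crossing test for proper segment intersection (shared endpoints of adjacent
# segments excluded by the caller)
segs_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polyline_self_intersects <- function(v, closed = FALSE) {
  if (closed) v <- rbind(v, v[1L, ])
  n <- nrow(v) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (closed && i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, jmax)) {
      if (segs_cross(v[i, ], v[i + 1L, ], v[j, ], v[j + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

#' Signed distance from points to a fold line
#'
#' For an open polyline the sign is that of the cross product against the
#' nearest segment (positive = left of the segment direction). For a closed
#' ring, positive means inside. Magnitude is the Euclidean distance to the
#' polyline.
#'
#' @param points two-column matrix (or length-2 vector) of positions in um.
#' @param fold a [fold_line()].
#' @return numeric vector of signed distances (um).
#' @export
signed_distance <- function(points, fold) {
  if (!inherits(fold, "fold_line")) stopf("'fold' must be a fold_line")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  seg <- fold_segments(fold)
  n_seg <- nrow(seg$a)
  out <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    p <- points[k, ]
    best_d <- Inf; best_cross <- 0
    for (i in seq_len(n_seg)) {
      a <- seg$a[i, ]; b <- seg$b[i, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
      proj <- a + t * ab
      d <- sqrt(sum((p - proj)^2))
      cr <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
      # ties at shared vertices: prefer the segment the point lies beside
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && abs(cr) > abs(best_cross))) {
        best_d <- d; best_cross <- cr
      }
    }
    out[k] <- if (best_cross < 0) -best_d else best_d
  }
  if (fold$closed) {
    inside <- mgcv::in.out(rbind(fold$vertices, fold$vertices[1L, ]), points)
    out <- ifelse(inside, abs(out), -abs(out))
  }
  out
}

#' Side-of-fold call for points
#'
#' @param points two-column matrix of positions (um).
#' @param fold a [fold_line()].
#' @param tol on-line tolerance in um (default 0.25, well under one cell
#'   diameter); points closer than this to the line are called `on-line`.
#' @return character vector in `{"A-side", "B-side", "on-line"}`. `A-side` is
#'   positive signed distance (inside, for closed folds).
#' @export
side_of_fold <- function(points, fold, tol = 0.25) {
  d <- signed_distance(points, fold)
  ifelse(abs(d) < tol, "on-line", ifelse(d > 0, "A-side", "B-side"))
}
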