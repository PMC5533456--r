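# Independent oracles used across tests; deliberately written as plain
# re-derivations, not calls into the code paths they check.

# brute-force re-evaluation of the three classification predicates,
# clause by clause
oracle_classify <- function(areas, fluct_delta = 10, lo = 20, hi = 40,
                            final_max = 10, w = 3L) {
  n <- length(areas)
  w <- min(w, n)
  initial <- mean(areas[1:w])
  final <- mean(areas[(n - w + 1):n])
  delta <- max(areas) - min(areas)
  if (initial >= lo && initial <= hi && final < final_max) return("decreasing")
  if (delta >= fluct_delta) return("fluctuating")
  "constant"
}

# plain nearest-segment signed distance, scalar loop
oracle_signed_distance <- function(p, vertices, closed = FALSE) {
  v <- vertices
  if (closed) v <- rbind(v, v[1, ])
  best <- Inf
  best_cross <- 0
  for (i in seq_len(nrow(v) - 1)) {
    a <- v[i, ]; b <- v[i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    pr <- a + t * ab
    d <- sqrt(sum((p - pr)^2))
    cr <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
    if (d < best - 1e-12 || (abs(d - best) <= 1e-12 && abs(cr) > abs(best_cross))) {
      best <- d
      best_cross <- cr
    }
  }
  if (best_cross < 0) -best else best
}

# voxel-counting volume of a solid of revolution with radius r_of_z(z)
oracle_voxel_volume <- function(r_of_z, z_lo, z_hi, r_max, g = 0.01) {
  xs <- seq(-r_max + g / 2, r_max - g / 2, by = g)
  r2_grid <- outer(xs^2, xs^2, `+`)
  zs <- seq(z_lo + g / 2, z_hi - g / 2, by = g)
  v <- 0
  for (z in zs) {
    r <- r_of_z(z)
    v <- v + sum(r2_grid <= r^2) * g^2 * g
  }
  v
}

# random positive trace for property tests
random_trace <- function(id, n = 30L) {
  cell_trace(id, seq(0, by = 5, length.out = n),
             runif(n, 1, 60))
}

# a stack of k-gon slices approximating a solid of revolution
polygon_stack_of_revolution <- function(cell_id, domain, r_of_z, z, k = 256L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  polys <- lapply(z, function(zz) {
    r <- max(r_of_z(zz), 1e-6)
    cbind(r * cos(th), r * sin(th))
  })
  contour_stack(cell_id, domain, z, polys)
}
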