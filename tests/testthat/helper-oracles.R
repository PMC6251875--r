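# Independent oracles used across the suite. These deliberately share no code
# with the implementation paths they check.

# Closed-form OLS through the normal equations.
normal_equation_fit <- function(X, y) {
  Xd <- cbind(1, X)
  solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
}

# Leave-one-out Q2 by literally refitting n models.
brute_force_q2 <- function(data, response, descriptors) {
  y <- data[[response]]
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    train <- data[-i, ]
    beta <- normal_equation_fit(as.matrix(train[descriptors]),
                                train[[response]])
    xi <- c(1, as.numeric(data[i, descriptors]))
    press <- press + (y[i] - sum(beta * xi))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Dense-grid numerical SASA for small systems (independent of the
# Fibonacci-quadrature path: random points, different acceptance loop).
dense_sasa <- function(xyz, radii, probe, n_points = 2e5, seed = 99) {
  set.seed(seed)
  r <- radii + probe
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    z <- stats::runif(n_points, -1, 1)
    th <- stats::runif(n_points, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pts <- cbind(s * cos(th), s * sin(th), z) * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))[-i]) {
      acc <- acc & ((pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
                      (pts[, 3] - xyz[j, 3])^2 > r[j]^2)
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# Exhaustive global alignment score with affine gaps (gap of length L costs
# open + L * ext), by recursion over all alignments of tiny sequences.
brute_force_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, submat[a[i], b[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(a)) {  # a[i] against a gap
      cost <- ext + if (last == "d") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "d"))
    }
    if (j <= length(b)) {
      cost <- ext + if (last == "i") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "i"))
    }
    best
  }
  rec(1, 1, "m")
}

# Analytic SASA of two equal intersecting spheres of expanded radius R at
# separation d (each sphere loses a cap of height h = R - d/2).
two_sphere_sasa <- function(R, d) {
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# regular planar carbon-ring coordinates used to assemble test molecules
ring_coords_for_test <- function(n, bond = 1.39) {
  r <- bond / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(ang), r * sin(ang), 0)
}
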