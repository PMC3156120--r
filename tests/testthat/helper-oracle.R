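# Independent oracles for the spherical geometry, kept free of the package's
# optimizer: exhaustive candidate enumeration for the smallest enclosing cap
# on S^2, and a dense-lattice search for the spherical standard deviation.

# smallest enclosing cap by enumerating 1-point, 2-point-midpoint and
# 3-point-equal-angle candidate centers and keeping the feasible minimum
oracle_cap <- function(D) {
  n <- nrow(D)
  best <- list(r = Inf, c = NULL)
  consider <- function(c0) {
    nc <- sqrt(sum(c0^2))
    if (nc < 1e-12) return()
    c0 <- c0 / nc
    r <- max(acos(pmax(-1, pmin(1, D %*% c0))))
    if (r < best$r) best <<- list(r = r, c = c0)
  }
  for (i in seq_len(n)) consider(D[i, ])
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      s <- D[i, ] + D[j, ]
      consider(s)
      consider(-s)
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      x <- tryCatch(solve(D[c(i, j, k), ], rep(1, 3)),
                    error = function(e) NULL)
      if (!is.null(x)) {
        consider(x)
        consider(-x)
      }
    }
  }
  list(radius_deg = best$r * 180 / pi, center = best$c)
}

# Fibonacci lattice on S^2
sphere_lattice <- function(n = 40000) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# spherical standard deviation by dense grid search (value accurate to well
# under 0.1 degrees; the RMS objective is smooth with O(1) curvature)
oracle_sd <- function(D, lattice = sphere_lattice()) {
  ang <- acos(pmax(pmin(lattice %*% t(D), 1), -1)) # keeps matrix dims
  rms <- sqrt(rowMeans(ang^2))
  min(rms) * 180 / pi
}

random_directions <- function(n, d = 3) {
  m <- matrix(rnorm(n * d), n)
  m / sqrt(rowSums(m^2))
}

random_rotation <- function(d) {
  qr_d <- qr(matrix(rnorm(d * d), d))
  q <- qr.Q(qr_d)
  q %*% diag(sign(diag(qr.R(qr_d))), d)
}
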