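# Independent oracles and small utilities shared across test files.

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Brute-force total-least-squares plane oracle: coarse search over normal
# directions on the unit sphere, refined by Nelder-Mead on spherical
# coordinates. For a fixed unit normal n the optimal offset puts the plane
# through the centroid, so the rms is sd of the projections n . x.
brute_force_plane_rms <- function(points) {
  X <- sweep(points, 2, colMeans(points))
  rms_for <- function(n) sqrt(mean((X %*% n)^2))
  rms_sph <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    rms_for(n)
  }
  # Fibonacci-lattice scan of the hemisphere
  k <- seq_len(2000)
  theta <- acos(1 - k / 2000)            # polar in [0, pi/2]-ish upper half
  phi <- pi * (1 + sqrt(5)) * k
  grid <- cbind(theta, phi %% (2 * pi))
  vals <- apply(grid, 1, rms_sph)
  best <- grid[which.min(vals), ]
  opt <- optim(best, rms_sph, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# Closed-form six-angle oracle written directly from the definitions, kept
# separate from the package's closed_form_angles(): components (l, a, c) of
# the unit axis along (lateral, anterior, cranial).
oracle_six_angles <- function(l, a, c) {
  r <- sqrt(l^2 + a^2 + c^2)
  l <- l / r; a <- a / r; c <- c / r
  deg <- function(x) x * 180 / pi
  sa <- if (a < 0) -1 else 1
  list(AI = deg(acos(abs(c))),
       AA = sa * deg(acos(l / sqrt(l^2 + a^2))),
       OI = deg(asin(l)),
       OA = sa * deg(atan2(abs(a), abs(c))),
       RI = deg(atan2(abs(l), abs(c))),
       RA = deg(asin(a)))
}

# canonical exact reference frame of the synthetic generator
canonical_frame <- function() {
  set <- generate_pelvis(synthetic_spec())$landmarks
  build_frame(set)
}

angle_cols <- c("AI", "AA", "OI", "OA", "RI", "RA")
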