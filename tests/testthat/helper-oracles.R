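# independent oracles used across the suite; deliberately written with
# different math than the implementation they check

# dihedral via explicit plane normals and a signed angle (Gram-Schmidt
# construction, no atan2-on-cross shortcut shared with the package code)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b1 - sum(b1 * b2) / sum(b2 * b2) * b2
  w <- b3 - sum(b3 * b2) / sum(b2 * b2) * b2
  cosang <- sum(u * w) / sqrt(sum(u * u) * sum(w * w))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  if (sum(cr * b2) < 0) ang <- -ang
  ang
}

# accessible area of two overlapping probe-inflated spheres, closed form
# (spherical caps); returns total accessible area of the pair
oracle_two_sphere_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  cap <- function(Ra, Rb) {
    # height of the cap of sphere a hidden inside sphere b
    h <- Ra - (d^2 + Ra^2 - Rb^2) / (2 * d)
    2 * pi * Ra * max(0, min(h, 2 * Ra))
  }
  4 * pi * R1^2 - cap(R1, R2) + 4 * pi * R2^2 - cap(R2, R1)
}

# brute-force all-pairs clash count on a backbone model
oracle_clash_count <- function(model, min_distance = 2.8) {
  n <- nrow(model$xyz)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(model$resno[i] - model$resno[j]) < 2) next
      if (sqrt(sum((model$xyz[i, ] - model$xyz[j, ])^2)) < min_distance) {
        cnt <- cnt + 1L
      }
    }
  }
  cnt
}

# direct-formula radius of gyration over CA atoms
oracle_rg <- function(model) {
  ca <- atom_coords(model, "CA")
  mu <- colMeans(ca)
  sqrt(sum(sweep(ca, 2, mu)^2) / nrow(ca))
}

# quasi-uniform points on a sphere (for building hollow-shell fixtures)
shell_points <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_rigid_transform <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(rotation = R, translation = stats::rnorm(3, sd = 5))
}

# apply a rigid transform to a backbone model
transform_model <- function(model, rt) {
  out <- model
  out$xyz <- transform_coords(model$xyz, rt$rotation, rt$translation)
  attr(out, "ranges") <- attr(model, "ranges")
  out
}

# a short mixed-torsion chain used by several geometry tests
fixture_chain <- function(n = 12, seed = 4) {
  set.seed(seed)
  tor <- cbind(phi = stats::runif(n, -180, 179),
               psi = stats::runif(n, -180, 179),
               omega = 180)
  build_chain_from_torsions(tor)
}
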