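# Shared fixtures built in code.

# A small asymmetric 8-point configuration (no symmetry, so reflections and
# rotations are distinguishable).
asym_shape <- function() {
  rbind(
    c(0, 0), c(2, 0.3), c(3.1, 1.2), c(2.4, 2.6),
    c(1.1, 3.0), c(-0.4, 2.1), c(-0.9, 0.8), c(0.6, 1.4)
  )
}

random_similarity <- function(m) {
  theta <- runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  s <- runif(1, 0.2, 5)
  shift <- runif(2, -10, 10)
  sweep(s * m %*% rot, 2, shift, `+`)
}

# Independent brute-force oracle: minimum Procrustes distance over a dense
# rotation grid, computed by explicit rotation and residual norm.
grid_procrustes_distance <- function(a, b, n_grid = 1e6) {
  au <- sweep(a, 2, colMeans(a)); au <- au / sqrt(sum(au^2))
  bu <- sweep(b, 2, colMeans(b)); bu <- bu / sqrt(sum(bu^2))
  thetas <- seq(0, 2 * pi, length.out = n_grid)
  best <- Inf
  for (th in thetas) {
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    d <- sqrt(sum((bu %*% r - au)^2))
    if (d < best) best <- d
  }
  best
}

# Write a throwaway CSV and return its path.
tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# A tiny wiggly suture polyline with a known layout.
square_wave_trace <- function() rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))

semicircle_polyline <- function(n = 2001) {
  th <- seq(0, pi, length.out = n)
  cbind(cos(th), sin(th))
}
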