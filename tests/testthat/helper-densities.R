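# Shared fixtures: analytic exponential-family densities with normalizers
# computed by stats::integrate (independent of the package's quadrature),
# and small track files written on the fly.

# f(x) propto exp(sum_i c_i * x_i) on the cube, as a maxent_density object.
make_exp_density <- function(cx = 0, cy = 0, cz = 0, k = 1, nodes = 24) {
  alpha <- enumerate_multi_indices(k)
  mv <- trajentropy:::new_moment_vector(alpha, c(1, rep(0, nrow(alpha) - 1)),
                                        k = k, n = 1L)
  lam <- setNames(rep(0, nrow(alpha) - 1),
                  paste0("x", alpha$a1, alpha$a2, alpha$a3)[-1])
  lam["x100"] <- cx
  lam["x010"] <- cy
  lam["x001"] <- cz
  z1 <- function(c) integrate(function(x) exp(c * x), -1, 1)$value
  structure(
    list(lambda = lam, log_partition = log(z1(cx) * z1(cy) * z1(cz)),
         k = k, nodes = nodes, converged = TRUE, iterations = 0L,
         moment_residual = 0, moments = mv),
    class = "maxent_density"
  )
}

# Moments of f propto exp(c * x1) up to order 2k, via 1-D integrate():
# axes are independent, so each 3-D moment is a product of 1-D moments.
exp_density_moments <- function(c1, k) {
  alpha <- enumerate_multi_indices(k)
  z <- integrate(function(x) exp(c1 * x), -1, 1)$value
  m_x <- function(j) integrate(function(x) x^j * exp(c1 * x), -1, 1)$value / z
  m_u <- function(j) if (j %% 2 == 0) 1 / (j + 1) else 0  # uniform on [-1,1]
  vals <- mapply(function(a, b, c) m_x(a) * m_u(b) * m_u(c),
                 alpha$a1, alpha$a2, alpha$a3)
  trajentropy:::new_moment_vector(alpha, vals, k = k, n = NA_integer_)
}

write_track_file <- function(lines, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

ln8 <- log(8)
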