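# Independent oracles used across the suite. They re-state the governing
# equations directly and solve them by brute force, deliberately avoiding the
# package's solvers.

# Water-flux residual of the implicit PRO equation, written out verbatim.
oracle_flux_residual <- function(J, pi_D, pi_F, P, mem) {
  mem$A * ((pi_D * exp(-J / mem$k) - pi_F * exp(J * mem$S_struct / mem$D)) /
             (1 + (mem$B / J) * (exp(J * mem$S_struct / mem$D) -
                                   exp(-J / mem$k))) - P) - J
}

# Locate the flux root by a dense two-stage grid scan over (0, A*pi_D]:
# find the sign change on a coarse grid, then refine within that cell. The
# two stages give the resolution of a ~4e8-point uniform grid.
oracle_grid_flux <- function(pi_D, pi_F, P, mem, n = 20001L) {
  hi <- mem$A * pi_D
  grid <- seq(hi / n, hi, length.out = n)
  r <- oracle_flux_residual(grid, pi_D, pi_F, P, mem)
  if (r[1] <= 0) return(0)          # no positive root: driving force gone
  i <- which(r <= 0)[1]
  if (is.na(i)) return(hi)
  fine <- seq(grid[i - 1], grid[i], length.out = n)
  rf <- oracle_flux_residual(fine, pi_D, pi_F, P, mem)
  j <- which(rf <= 0)[1]
  # linear interpolation across the final sign change
  (fine[j - 1] * rf[j] - fine[j] * rf[j - 1]) / (rf[j] - rf[j - 1])
}

# Fixed-step classical Runge-Kutta integration of a single-population Monod
# depletion with growth/decay (the exoelectrogen-only, current-free limit of
# the anode model): dS/dt = -q S/(K+S) x,  dx/dt = (mu S/(K+S) - d) x.
oracle_monod_rk4 <- function(S0, x0, q, K, mu, d, t_end_d, dt_d = 1e-4) {
  f <- function(y) {
    mon <- y[1] / (K + y[1])
    c(-q * mon * y[2], (mu * mon - d) * y[2])
  }
  y <- c(S0, x0)
  n <- ceiling(t_end_d / dt_d)
  h <- t_end_d / n
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Random, physically admissible flux-problem draws for the solver/oracle
# comparison.
draw_flux_cases <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mem <- pro_membrane(A = 10^runif(1, -7.5, -6.5),
                        B = 10^runif(1, -8, -6.5),
                        S_struct = 10^runif(1, -4, -2.8),
                        D = 1.5e-9,
                        k = 10^runif(1, -5, -4.3))
    pi_F <- runif(1, 0, 4)
    pi_D <- pi_F + runif(1, 1, 95)
    P <- runif(1, 0, pi_D / 3)
    list(mem = mem, pi_D = pi_D, pi_F = pi_F, P = P)
  })
}
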