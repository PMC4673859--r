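# Independent oracles used by the tests. These deliberately do not touch the
# package's propagation or calibration code paths.

# Planar random-walk endpoint in a reflecting square [0, L]^2: specular
# reflection off axis-aligned walls is coordinate-wise triangle-wave folding.
fold_into_square <- function(p, L) {
  f <- function(x) {
    x <- x %% (2 * L)
    ifelse(x > L, 2 * L - x, x)
  }
  c(f(p[1]), f(p[2]))
}

# Stationary slow:fast occupancy ratio of a 1-D two-zone random walk with the
# same step rule as the simulator (whole step at the start-position D,
# reflecting ends). Domain [0, 2L]: fast zone [0, L), slow zone [L, 2L].
two_zone_ratio_1d <- function(D_fast, D_slow, L = 1, dt = 1e-3, n = 3000,
                              t_total = 400, burn = 200, sample_every = 20) {
  sfast <- sqrt(2 * D_fast * dt)
  sslow <- sqrt(2 * D_slow * dt)
  x <- runif(n, 0, 2 * L)
  nstep <- round(t_total / dt)
  bstep <- round(burn / dt)
  slow_acc <- 0; fast_acc <- 0
  for (i in seq_len(nstep)) {
    x <- x + rnorm(n) * (sslow + (sfast - sslow) * (x < L))
    x <- abs(x)
    x <- 2 * L - abs(2 * L - x)
    if (i > bstep && i %% sample_every == 0) {
      ns <- sum(x >= L)
      slow_acc <- slow_acc + ns
      fast_acc <- fast_acc + (n - ns)
    }
  }
  slow_acc / fast_acc
}

# Brute-force well-mixed rate recovery: independent pairs whose relative
# coordinate random-walks in a periodic square whose area matches the
# calibration's far-field screening disc; pairs are re-drawn uniformly after
# each capture so the bulk stays well mixed.
mc_rate_recovery <- function(k, D_mutual, dt, sigma_b, far_field = 10,
                             n = 2000, nstep = 3000) {
  s <- sqrt(2 * D_mutual * dt)
  L <- sqrt(pi) * (sigma_b + far_field * s)
  x <- runif(n, -L / 2, L / 2); y <- runif(n, -L / 2, L / 2)
  events <- 0
  for (i in seq_len(nstep)) {
    x <- x + rnorm(n, 0, s); y <- y + rnorm(n, 0, s)
    x <- x - L * round(x / L); y <- y - L * round(y / L)
    hit <- x * x + y * y <= sigma_b^2
    ne <- sum(hit)
    if (ne) {
      events <- events + ne
      x[hit] <- runif(ne, -L / 2, L / 2)
      y[hit] <- runif(ne, -L / 2, L / 2)
    }
  }
  events / (n * nstep * dt) * L^2
}

# Brute-force geminate recombination: pairs released at separation sigma_u,
# relative 2-D walk until capture (r < sigma_b) or escape
# (r > sigma_b + escape rms steps); returns the recombined fraction.
mc_recombination_fraction <- function(sigma_u, sigma_b, D_mutual, dt,
                                      escape = 12, n = 10000,
                                      max_steps = 200000) {
  s <- sqrt(2 * D_mutual * dt)
  r_esc <- sigma_b + escape * s
  phi <- runif(n, 0, 2 * pi)
  x <- sigma_u * cos(phi); y <- sigma_u * sin(phi)
  alive <- rep(TRUE, n)
  rec <- 0
  for (i in seq_len(max_steps)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    x[idx] <- x[idx] + rnorm(length(idx), 0, s)
    y[idx] <- y[idx] + rnorm(length(idx), 0, s)
    r2 <- x[idx]^2 + y[idx]^2
    hit <- r2 <= sigma_b^2
    esc <- r2 >= r_esc^2
    rec <- rec + sum(hit)
    alive[idx[hit | esc]] <- FALSE
  }
  rec / n
}

# Closed-form well-mixed solution of A + B -> C with equal initial copy
# numbers n0 in area A (2-D mass action): n(t) = n0 / (1 + n0 k t / A).
ode_pair_decay <- function(n0, k, area, t) n0 / (1 + n0 * k * t / area)
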