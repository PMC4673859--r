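# Surface-indexed diffusion table and Brownian step sampling.

test_that("lookup returns the per-surface override, else the default", {
  tab <- diffusion_table()
  tab <- set_difc(tab, "AMPAR", 0.45)
  tab <- set_surface_difc(tab, "psd", "AMPAR", 0.45e-5)
  expect_equal(lookup_difc(tab, "AMPAR", "surface", "psd"), 0.45e-5)
  expect_equal(lookup_difc(tab, "AMPAR", "surface", "esm"), 0.45)
  expect_error(lookup_difc(tab, "X", "surface", "psd"), "undeclared")
  expect_error(lookup_difc(tab, "AMPAR", "cytosolic", "psd"), "undeclared")
  expect_error(set_difc(tab, "AMPAR", -1), ">= 0")
  # an override needs a declared default
  expect_error(set_surface_difc(tab, "psd", "GHOST", 1), "no default")
  # states are independent table entries
  tab <- set_difc(tab, "AMPAR", 0.1, state = "clustered")
  expect_equal(lookup_difc(tab, "AMPAR", "clustered", "psd"), 0.1)
  expect_equal(lookup_difc(tab, "AMPAR", "surface", "psd"), 0.45e-5)
})

test_that("step sampling has the closed-form spread", {
  sam <- step_sampler(1e-3)
  expect_equal(sample_step(sam, 0), c(0, 0))
  set.seed(1)
  st <- sample_step(sam, 0.45, n = 1e5)
  v <- c(var(st[, 1]), var(st[, 2]))
  expect_equal(v, rep(2 * 0.45 * 1e-3, 2), tolerance = 0.02)
  expect_error(sample_step(sam, -0.1), ">= 0")
  expect_error(step_sampler(0), "> 0")
})

test_that("a step uses the D of the panel the molecule starts on", {
  m <- build_mesh(list(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                       rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 0))),
                  c("fast", "slow"))
  tab <- set_difc(diffusion_table(), "A", 0.1)
  tab <- set_surface_difc(tab, "slow", "A", 0.001)
  sam <- step_sampler(1e-3)
  # empirical per-surface step variance matches each assigned coefficient
  for (cfg in list(list(panel = 1, D = 0.1), list(panel = 2, D = 0.001))) {
    start <- surface_position(cfg$panel, bary_to_local(m, cfg$panel, c(1, 1, 1)))
    w0 <- to_world(start, m)
    set.seed(42)
    d2 <- replicate(1e4, {
      pos <- diffuse_molecule(start, "A", "surface", tab, m, sam)
      sum((to_world(pos, m) - w0)^2)
    })
    # E|step|^2 = 4 D dt (crossings preserve path length, and at dt = 1 ms
    # steps rarely reflect at this distance from the edges)
    expect_equal(mean(d2), 4 * cfg$D * 1e-3, tolerance = 0.05)
  }
})

test_that("equal seeds give identical step sequences", {
  m <- build_mesh(list(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                       rbind(c(0, 0, 0), c(1, 1, 0), c(0, 1, 0))),
                  c("fast", "slow"))
  tab <- set_difc(diffusion_table(), "A", 0.1)
  tab <- set_surface_difc(tab, "slow", "A", 0.001)
  sam <- step_sampler(1e-3)
  walk <- function(seed) {
    set.seed(seed)
    pos <- surface_position(1, c(0.5, 0.2))
    out <- matrix(0, 200, 3)
    for (i in 1:200) {
      pos <- diffuse_molecule(pos, "A", "surface", tab, m, sam)
      out[i, ] <- to_world(pos, m)
    }
    out
  }
  expect_identical(walk(99), walk(99))
  expect_false(identical(walk(99), walk(100)))
})
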