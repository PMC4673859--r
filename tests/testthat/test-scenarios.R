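# Scenario generators and trajectory/count analysis.

test_that("two-triangle scenario encodes the heterogeneous plane", {
  cfg <- scenario_two_triangle()
  expect_equal(cfg$difc$A, 0.1)
  expect_equal(cfg$surface_difc$D, 0.001)          # hundredfold contrast
  plan <- validate_config(cfg)
  expect_equal(plan$mesh$nsurf, 2)
  expect_equal(unname(plan$mesh$surface_area), c(0.5, 0.5))

  # homogeneous control: equal coefficients on both triangles
  h <- validate_config(scenario_two_triangle(D_fast = 0.05, D_slow = 0.05))
  expect_equal(unname(h$D[1, ]), c(0.05, 0.05))
})

test_that("crossing disabled keeps every molecule on its starting surface", {
  cfg <- scenario_two_triangle(n_molecules = 20, crossing = FALSE,
                               time_stop = 2)
  res <- run_simulation(cfg, seed = 21)
  per_id <- split(res$traj$surface, res$traj$id)
  expect_true(all(vapply(per_id, function(s) length(unique(s)) == 1,
                         logical(1))))
  # with crossing on, some molecules do change surface
  res2 <- run_simulation(scenario_two_triangle(n_molecules = 20,
                                               time_stop = 2), seed = 21)
  per_id2 <- split(res2$traj$surface, res2$traj$id)
  expect_true(any(vapply(per_id2, function(s) length(unique(s)) > 1,
                         logical(1))))
})

test_that("phosphorylation scenario starts 3 kinases and 500 PIP2 per triangle", {
  cfg <- scenario_pip()
  res <- run_simulation(cfg, seed = 1)
  t0 <- res$counts[res$counts$time == 0, ]
  get <- function(sp, srf) t0$count[t0$species == sp & t0$surface == srf]
  expect_equal(get("PIP2", "fast"), 500)
  expect_equal(get("PIP2", "slow"), 500)
  expect_equal(get("PI3K", "fast"), 3)
  expect_equal(get("PI3K", "slow"), 3)
  expect_equal(get("PIP3", "fast"), 0)
  expect_equal(get("PIP3", "slow"), 0)
})

test_that("a dead kinase reaction produces no product", {
  cfg <- scenario_pip(k = 0, time_stop = 2)
  res <- run_simulation(cfg, seed = 2)
  expect_true(all(res$counts$count[res$counts$species == "PIP3"] == 0))
})

test_that("spine scenario: copy numbers, PSD share, and immobile scaffolds", {
  cfg <- scenario_spine(with_scaffold = TRUE, time_stop = 0)
  expect_equal(cfg$difc$AMPAR, 0.45)
  expect_equal(cfg$placements$n, c(66L, 132L))
  plan <- validate_config(cfg)
  share <- plan$mesh$surface_area["psd"] / sum(plan$mesh$surface_area)
  expect_gt(share, 0.07); expect_lt(share, 0.14)
  # scaffolds sit inside the PSD and never move
  res <- run_simulation(scenario_spine(with_scaffold = TRUE, time_stop = 1,
                                       k_on = 0),
                        seed = 6)
  sc <- res$counts[res$counts$species == "Scaffold", ]
  expect_true(all(sc$count[sc$surface == "psd"] == 132))
})

test_that("MSD: degenerate input is flagged, free diffusion fits 4 D", {
  still <- data.frame(time = seq(0, 1, by = 0.1), id = 1L, x = 1, y = 2, z = 0)
  m0 <- msd(still)
  expect_true(m0$degenerate)
  expect_true(is.na(m0$alpha))
  expect_error(msd(still, lags = 50), "exceeds trajectory length")
  expect_error(msd(data.frame(time = c(0, 0.1, 0.4), id = 1L,
                              x = 0, y = 0, z = 0)), "uniform sampling")

  res <- run_simulation(scenario_free_plane(n_molecules = 300, time_stop = 5),
                        seed = 13)
  mm <- msd(res$traj)
  expect_equal(mm$slope, 4 * 0.45, tolerance = 0.07)
  expect_equal(mm$alpha, 1, tolerance = 0.05)
})

test_that("enrichment tracks region occupancy and bound complexes", {
  counts <- data.frame(
    time = rep(c(0, 1), each = 4),
    species = rep(c("A", "A", "AB", "AB"), 2),
    surface = rep(c("psd", "esm"), 4),
    count = c(10, 0, 0, 0,   2, 4, 4, 0))
  e <- enrichment(counts, "A", "psd", bound_species = "AB")
  expect_equal(e$fraction, c(1, (2 + 4) / 10))
  expect_error(enrichment(counts, "A", "nope"), "unknown surface")
  b <- bound_fraction(counts, complex = "AB", free = "A")
  expect_equal(b$fraction, c(0, 0.4))
  expect_equal(time_to_threshold(b, 0.4), 1)
  expect_true(is.na(time_to_threshold(b, 0.9)))
})

test_that("uniform diffusion equilibrates to the PSD area fraction", {
  cfg <- scenario_spine(D_psd = 0.45, time_stop = 40, seed = NULL)
  plan <- validate_config(cfg)
  share <- unname(plan$mesh$surface_area["psd"] / sum(plan$mesh$surface_area))
  fr <- vapply(1:4, function(s) {
    res <- run_simulation(plan, seed = s)
    e <- enrichment(res$counts, "AMPAR", "psd")
    mean(e$fraction[e$time >= 10])
  }, numeric(1))
  # 66 receptors x 4 seeds x 30 s of samples: expect the area fraction
  expect_equal(mean(fr), share, tolerance = 0.2)
})

test_that("diffusive trapping first accumulates receptors near the PSD edge", {
  # under pure trapping, early in-PSD receptors cluster at the boundary of
  # the subarea relative to a uniform-in-PSD placement
  plan <- validate_config(scenario_spine(D_psd = 0.45e-4, time_stop = 4))
  theta_of <- function(traj) acos(pmin(1, pmax(-1, traj$z / 0.5)))
  plan$track <- TRUE
  obs <- unlist(lapply(1:6, function(s) {
    res <- run_simulation(plan, seed = s)
    tr <- res$traj[res$traj$surface == "psd" & res$traj$time >= 2, ]
    theta_of(tr)
  }))
  # uniform placement within the PSD cap, same count
  plan_u <- validate_config(scenario_spine(D_psd = 0.45e-4, time_stop = 0))
  set.seed(99)
  rp <- random_positions(plan_u$mesh, 20000, "psd")
  zu <- vapply(seq_along(rp$panel), function(i)
    to_world(surface_position(rp$panel[i], rp$local[i, ]), plan_u$mesh)[3],
    numeric(1))
  theta_u <- acos(pmin(1, pmax(-1, zu / 0.5)))
  expect_gt(mean(obs), mean(theta_u))
})
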