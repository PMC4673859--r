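# Reaction parameter calibration and the bimolecular pair rule.

unit_square_mesh <- function(L = 1, labels = "plane") {
  build_mesh(list(rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0)),
                  rbind(c(0, 0, 0), c(L, L, 0), c(0, L, 0))), labels)
}

test_that("first-order per-step probability is the exponential discretisation", {
  expect_equal(unimolecular_prob(0, 1e-3), 0)
  expect_equal(unimolecular_prob(log(2), 1), 0.5)
  ks <- 10^seq(-2, 1.5, by = 0.5)
  p <- vapply(ks, unimolecular_prob, numeric(1), dt = 1)
  expect_true(all(diff(p) > 0))
  expect_lt(1 - unimolecular_prob(1e4, 1), 1e-6)
  expect_error(unimolecular_prob(-1, 1e-3), "negative")
})

test_that("binding radius is zero at k = 0 and strictly increasing in k", {
  expect_equal(binding_radius_from_rate(0, 1, 1e-3), 0)
  sb <- vapply(c(0.5, 1, 2), binding_radius_from_rate, numeric(1),
               D_mutual = 2, dt = 1e-3)
  expect_true(all(diff(sb) > 0))
  expect_error(binding_radius_from_rate(-1, 1, 1e-3), "negative")
  expect_error(binding_radius_from_rate(1, 0, 1e-3), "D_mutual")
})

test_that("unbinding radius sits above the binding radius and shrinks with pgem", {
  sb <- binding_radius_from_rate(1, 2, 1e-3)
  su <- vapply(c(0.05, 0.2, 0.5), unbinding_radius_from_pgem, numeric(1),
               sigma_b = sb, D_mutual = 2, dt = 1e-3)
  expect_true(all(su >= sb))
  expect_true(all(diff(su) < 0))   # higher pgem -> release closer to contact
  expect_error(unbinding_radius_from_pgem(1, sb, 2, 1e-3), "pgem")
})

test_that("simulated product pairs recombine at the requested probability", {
  sb <- binding_radius_from_rate(1, 2, 1e-3)
  pgem <- 0.2
  su <- unbinding_radius_from_pgem(pgem, sb, 2, 1e-3)
  set.seed(2024)
  n <- 1e4
  frac <- mc_recombination_fraction(su, sb, 2, 1e-3, n = n)
  se <- sqrt(pgem * (1 - pgem) / n)
  expect_lt(abs(frac - pgem), 3 * se + 0.01)  # 3 SE plus grid discretisation
})

test_that("reaction tables derive per-surface radii from local mobility", {
  cfg <- scenario_pip()
  plan <- validate_config(cfg)
  sigb <- plan$rtable$reactions$phos$sigb
  # slower encounters must be compensated by a larger capture radius
  expect_gt(sigb["slow", "slow"], sigb["fast", "fast"])
  # cross-surface pairs use each molecule's own mobility
  expect_equal(sigb["fast", "slow"], sigb["slow", "fast"])
  expect_true(sigb["fast", "fast"] < sigb["fast", "slow"])

  # single uniform surface reduces to the surface-agnostic computation
  m1 <- unit_square_mesh()
  tab <- set_difc(set_difc(diffusion_table(), "A", 0.1), "B", 0.1)
  tab <- set_difc(tab, "C", 0.1)
  rt <- compute_reaction_tables(list(reaction("r", c("A", "B"), "C", 0.006)),
                                tab, m1, 1e-3)
  expect_equal(unname(rt$reactions$r$sigb[1, 1]),
               binding_radius_from_rate(0.006, 0.2, 1e-3))

  # a dead reaction schedules nothing
  rt0 <- compute_reaction_tables(list(reaction("r", c("A", "B"), "C", 0)),
                                 tab, m1, 1e-3)
  expect_true(all(rt0$reactions$r$sigb == 0))
})

test_that("bimolecular pair rule: capture radius, stoichiometry, once per step", {
  m <- unit_square_mesh()
  ent <- list(name = "r", order = 2, reactants = c("A", "B"), products = "C",
              rate = 1, pgem = 0.2, prob = NULL, rate0 = NULL,
              sigb = matrix(0.05, 1, 1, dimnames = list("plane", "plane")),
              sigu2 = NULL, sigu1 = NULL)
  tab <- structure(list(reactions = list(r = ent), dt = 1e-3,
                        surfaces = "plane"), class = "reaction_table")
  mol <- data.frame(id = 1:3, species = c("A", "B", "B"), panel = 1L,
                    lx = c(0.5, 0.54, 0.8), ly = c(0.1, 0.1, 0.1))
  res <- apply_bimolecular(mol, "r", tab, m)
  # only the close pair reacts; the far B survives
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$id_a, 1)
  expect_equal(res$events$id_b, 2)
  expect_equal(sort(res$molecules$species), c("B", "C"))
  # single product at the midpoint
  cpos <- res$molecules[res$molecules$species == "C", ]
  expect_equal(c(cpos$lx, cpos$ly), c(0.52, 0.1), tolerance = 1e-12)
  # nothing within range -> no events
  far <- data.frame(id = 1:2, species = c("A", "B"), panel = 1L,
                    lx = c(0.1, 0.9), ly = c(0.05, 0.05))
  expect_equal(nrow(apply_bimolecular(far, "r", tab, m)$events), 0)
  # one A among two candidate Bs reacts exactly once, with the nearer B
  both <- data.frame(id = 1:3, species = c("A", "B", "B"), panel = 1L,
                     lx = c(0.5, 0.53, 0.52), ly = c(0.1, 0.1, 0.1))
  res2 <- apply_bimolecular(both, "r", tab, m)
  expect_equal(nrow(res2$events), 1)
  expect_equal(res2$events$id_b, 3)
})

test_that("well-mixed A + B -> C follows the mass-action solution", {
  L <- 3
  cfg <- .surfdiff_test_pair_config(L)
  res <- run_simulation(cfg, seed = 31)
  a_t <- with(res$counts, tapply(count[species == "A"], time[species == "A"], sum))
  times <- as.numeric(names(a_t))
  thalf <- L^2 / (500 * 0.05)
  sel <- which.min(abs(times - thalf))
  expected <- ode_pair_decay(500, 0.05, L^2, times[sel])
  expect_equal(unname(a_t[sel]), expected, tolerance = 0.1)
})

test_that("first-order decay leaves e^-1 survivors at t = 1/k", {
  cfg <- .surfdiff_test_decay_config(n = 2000, k = 1)
  res <- run_simulation(cfg, seed = 8)
  survivors <- sum(res$counts$count[res$counts$species == "A" &
                                      res$counts$time == 1])
  mu <- 2000 * exp(-1)
  expect_lt(abs(survivors - mu), 3 * sqrt(2000 * exp(-1) * (1 - exp(-1))))
})
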