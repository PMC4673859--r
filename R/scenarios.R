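# Built-in scenario generators. Each returns a ready-to-run surfdiff_config;
# all inputs are produced programmatically. Defaults: the heterogeneous plane
# is a 1 x 1 um square split along its diagonal into a "fast" and a "slow"
# triangle with a hundredfold diffusion contrast; the spine is a triangulated
# spherical head (radius 0.5 um) with a neck opening and a PSD cap covering
# ~10% of the head area.

.new_config <- function(species, difc, surface_difc = NULL, surfaces,
                        reactions = list(), placements = NULL,
                        confine = character(0), time_start = 0, time_stop,
                        time_step, random_seed = NULL, output_interval = 1L,
                        outputs = list()) {
  structure(list(
    species = species, difc = difc,
    surface_difc = surface_difc %||%
      data.frame(surface = character(0), species = character(0),
                 D = numeric(0), stringsAsFactors = FALSE),
    surfaces = surfaces, reactions = reactions,
    placements = placements %||%
      data.frame(n = integer(0), species = character(0),
                 surface = character(0), stringsAsFactors = FALSE),
    confine = confine, time_start = time_start, time_stop = time_stop,
    time_step = time_step, random_seed = random_seed,
    output_interval = as.integer(output_interval), outputs = outputs),
    class = "surfdiff_config")
}

.two_triangle_surfaces <- function(L) {
  list(fast = list(matrix(c(0, 0, 0, L, 0, 0, L, L, 0), 3, 3, byrow = TRUE)),
       slow = list(matrix(c(0, 0, 0, L, L, 0, 0, L, 0), 3, 3, byrow = TRUE)))
}

#' Two-triangle heterogeneous plane scenario
#'
#' A square plane split along its diagonal into a `fast` and a `slow`
#' triangular surface; the species' default coefficient is `D_fast` and a
#' `surface_difc` override sets `D_slow` on the slow triangle. With
#' `crossing = FALSE` the species is confined, making the diagonal
#' reflective; outer boundaries are always reflective.
#'
#' @param D_fast,D_slow diffusion coefficients (um^2/s); default contrast is
#'   hundredfold.
#' @param n_molecules molecules placed uniformly over the whole plane.
#' @param crossing allow crossing between the two triangles.
#' @param L side length (um).
#' @param species species name.
#' @param time_stop,time_step,output_interval run control (s, s, steps).
#' @param seed optional `random_seed` embedded in the config.
#' @param trajectory also record trajectories of all molecules.
#' @return a `surfdiff_config`.
#' @export
scenario_two_triangle <- function(D_fast = 0.1, D_slow = 0.001,
                                  n_molecules = 1, crossing = TRUE, L = 1,
                                  species = "A", time_stop = 100,
                                  time_step = 1e-3, output_interval = 100,
                                  seed = NULL, trajectory = TRUE) {
  stopifnot(D_fast >= 0, D_slow >= 0)
  outputs <- list(list(type = "counts", file = "counts.tsv"))
  if (trajectory)
    outputs <- c(outputs, list(list(type = "trajectory", species = "all",
                                    file = "traj.tsv")))
  .new_config(
    species = species,
    difc = setNames(list(D_fast), species),
    surface_difc = data.frame(surface = "slow", species = species,
                              D = D_slow, stringsAsFactors = FALSE),
    surfaces = .two_triangle_surfaces(L),
    placements = data.frame(n = as.integer(n_molecules), species = species,
                            surface = "all", stringsAsFactors = FALSE),
    confine = if (crossing) character(0) else species,
    time_stop = time_stop, time_step = time_step, random_seed = seed,
    output_interval = output_interval, outputs = outputs)
}

#' Homogeneous free-diffusion plane
#'
#' A large square plane (single surface) for testing the free-diffusion MSD
#' law MSD = 4 D tau without boundary saturation.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param n_molecules particles placed uniformly.
#' @param L side length (um); choose L >> sqrt(4 D t_stop).
#' @inheritParams scenario_two_triangle
#' @export
scenario_free_plane <- function(D = 0.45, n_molecules = 1000, L = 50,
                                species = "A", time_stop = 10,
                                time_step = 1e-3, output_interval = 10,
                                seed = NULL) {
  .new_config(
    species = species,
    difc = setNames(list(D), species),
    surfaces = list(plane = .two_triangle_surfaces(L)$fast |>
                      c(.two_triangle_surfaces(L)$slow)),
    placements = data.frame(n = as.integer(n_molecules), species = species,
                            surface = "all", stringsAsFactors = FALSE),
    time_stop = time_stop, time_step = time_step, random_seed = seed,
    output_interval = output_interval,
    outputs = list(list(type = "trajectory", species = "all",
                        file = "traj.tsv")))
}

#' Surface phosphorylation scenario (PIP2 + PI3K -> PIP3 + PI3K)
#'
#' The two-triangle plane with a kinase reaction: 3 PI3K and 500 PIP2 per
#' triangle, fast/slow diffusion contrast, reflective outer boundaries. PI3K
#' is always confined to its triangle; with `crossing = FALSE` PIP2 (and
#' PIP3) are confined too, mirroring runs in which molecules may not move
#' between the fast and slow triangles.
#'
#' @param k phosphorylation rate constant (um^2/s). The underlying kinetic
#'   parameters are not fixed by the model; the default is chosen so roughly
#'   half the substrate on the fast triangle reacts within ~20 s.
#' @param crossing allow PIP2/PIP3 to cross between triangles.
#' @param n_pip2,n_pi3k initial copy numbers per triangle.
#' @inheritParams scenario_two_triangle
#' @export
scenario_pip <- function(k = 0.006, crossing = FALSE, D_fast = 0.1,
                         D_slow = 0.001, L = 1, n_pip2 = 500, n_pi3k = 3,
                         time_stop = 30, time_step = 1e-3,
                         output_interval = 100, seed = NULL) {
  stopifnot(k >= 0)
  sp <- c("PIP2", "PIP3", "PI3K")
  .new_config(
    species = sp,
    difc = setNames(as.list(rep(D_fast, 3)), sp),
    surface_difc = data.frame(surface = "slow", species = sp, D = D_slow,
                              stringsAsFactors = FALSE),
    surfaces = .two_triangle_surfaces(L),
    reactions = list(reaction("phos", c("PIP2", "PI3K"),
                              c("PIP3", "PI3K"), k)),
    placements = data.frame(
      n = as.integer(c(n_pip2, n_pip2, n_pi3k, n_pi3k)),
      species = c("PIP2", "PIP2", "PI3K", "PI3K"),
      surface = c("fast", "slow", "fast", "slow"),
      stringsAsFactors = FALSE),
    confine = if (crossing) "PI3K" else c("PI3K", "PIP2", "PIP3"),
    time_stop = time_stop, time_step = time_step, random_seed = seed,
    output_interval = output_interval,
    outputs = list(list(type = "counts", file = "counts.tsv")))
}

#' Parametric spine-head mesh
#'
#' A triangulated sphere of radius `radius` with a neck opening (polar cap of
#' half-angle `neck_angle_deg` removed at the bottom; its rim is a reflective
#' boundary) and a `psd` polar cap at the top sized to `psd_fraction` of the
#' remaining head area; the rest is labelled `esm`.
#'
#' @param radius head radius (um).
#' @param neck_angle_deg neck opening half-angle (degrees).
#' @param psd_fraction target PSD share of head area.
#' @param n_theta,n_phi triangulation resolution (rings, segments).
#' @return list with `panels` (vertex matrices) and `surfaces` (labels).
#' @export
spine_mesh <- function(radius = 0.5, neck_angle_deg = 20, psd_fraction = 0.1,
                       n_theta = 12, n_phi = 16) {
  theta_max <- pi - neck_angle_deg * pi / 180
  cos_psd <- 1 - psd_fraction * (1 - cos(theta_max))
  theta_psd <- acos(cos_psd)
  th <- theta_max * seq(0, n_theta) / n_theta
  ph <- 2 * pi * seq(0, n_phi - 1) / n_phi
  # shared vertex coordinates computed once so edge matching is exact
  pt <- function(i, j) {
    j <- (j - 1) %% n_phi + 1
    radius * c(sin(th[i + 1]) * cos(ph[j]), sin(th[i + 1]) * sin(ph[j]),
               cos(th[i + 1]))
  }
  pole <- c(0, 0, radius)
  panels <- list(); cent_th <- numeric(0)
  for (j in seq_len(n_phi)) {
    panels <- c(panels, list(rbind(pole, pt(1, j), pt(1, j + 1))))
    cent_th <- c(cent_th, mean(c(0, th[2], th[2])))
  }
  for (i in seq_len(n_theta - 1)) {
    for (j in seq_len(n_phi)) {
      a <- pt(i, j); b <- pt(i + 1, j); cc <- pt(i + 1, j + 1); d <- pt(i, j + 1)
      panels <- c(panels, list(rbind(a, b, cc), rbind(a, cc, d)))
      cent_th <- c(cent_th, mean(c(th[i + 1], th[i + 2], th[i + 2])),
                   mean(c(th[i + 1], th[i + 2], th[i + 1])))
    }
  }
  list(panels = panels,
       surfaces = ifelse(cent_th < theta_psd, "psd", "esm"))
}

#' AMPA-receptor trapping scenario on a spine head
#'
#' A spherical spine-head surface with a `psd` cap and surrounding `esm`;
#' 66 AMPAR diffuse at `D_esm` with a per-surface override `D_psd` at the
#' PSD. With `with_scaffold = TRUE`, 132 immobile scaffold molecules are
#' placed uniformly in the PSD and AMPAR binds them reversibly
#' (AMPAR + Scaffold <-> AMPAR_Scaffold); the bound complex is immobile.
#'
#' @param D_psd AMPAR diffusion coefficient at the PSD (um^2/s).
#' @param D_esm AMPAR diffusion coefficient elsewhere (um^2/s).
#' @param with_scaffold add explicit scaffold binding.
#' @param n_ampar,n_scaffold copy numbers.
#' @param k_on,k_off scaffold binding/unbinding rates (um^2/s, 1/s); the
#'   source model's constants are not printed, so these are exposed
#'   parameters with documented defaults.
#' @param pgem geminate-recombination probability for unbinding placement.
#' @param radius,neck_angle_deg,psd_fraction,n_theta,n_phi mesh parameters,
#'   see [spine_mesh()].
#' @inheritParams scenario_two_triangle
#' @export
scenario_spine <- function(D_psd = 0.45, D_esm = 0.45, with_scaffold = FALSE,
                           n_ampar = 66, n_scaffold = 132, k_on = 0.01,
                           k_off = 0.001, pgem = 0.2, radius = 0.5,
                           neck_angle_deg = 20, psd_fraction = 0.1,
                           n_theta = 12, n_phi = 16, time_stop = 60,
                           time_step = 1e-3, output_interval = 100,
                           seed = NULL) {
  stopifnot(D_psd >= 0, D_esm >= 0)
  sm <- spine_mesh(radius, neck_angle_deg, psd_fraction, n_theta, n_phi)
  surfaces <- list(psd = sm$panels[sm$surfaces == "psd"],
                   esm = sm$panels[sm$surfaces == "esm"])
  species <- "AMPAR"
  difc <- list(AMPAR = D_esm)
  reactions <- list()
  placements <- data.frame(n = as.integer(n_ampar), species = "AMPAR",
                           surface = "all", stringsAsFactors = FALSE)
  if (with_scaffold) {
    species <- c("AMPAR", "Scaffold", "AMPAR_Scaffold")
    difc <- list(AMPAR = D_esm, Scaffold = 0, AMPAR_Scaffold = 0)
    reactions <- list(
      reaction("bind", c("AMPAR", "Scaffold"), "AMPAR_Scaffold", k_on,
               pgem = pgem),
      reaction("unbind", "AMPAR_Scaffold", c("AMPAR", "Scaffold"), k_off,
               pgem = pgem))
    placements <- rbind(placements,
                        data.frame(n = as.integer(n_scaffold),
                                   species = "Scaffold", surface = "psd",
                                   stringsAsFactors = FALSE))
  }
  .new_config(
    species = species, difc = difc,
    surface_difc = data.frame(surface = "psd", species = "AMPAR", D = D_psd,
                              stringsAsFactors = FALSE),
    surfaces = surfaces, reactions = reactions, placements = placements,
    time_stop = time_stop, time_step = time_step, random_seed = seed,
    output_interval = output_interval,
    outputs = list(list(type = "counts", file = "counts.tsv")))
}
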