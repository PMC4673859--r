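# The surface-indexed diffusion table and per-step Brownian displacements.
#
# A species' default diffusion coefficient applies everywhere unless a
# per-surface override exists: lookup returns the override for
# (species, state, surface) when present, otherwise the default for
# (species, state). Storage grows as (species x states) x surfaces.

.dt_key <- function(species, state) paste(species, state, sep = "\r")

#' Create an empty diffusion table
#'
#' Holds default per-(species, state) diffusion coefficients plus per-surface
#' overrides, all in um^2/s.
#'
#' @return an object of class `diffusion_table`.
#' @examples
#' tab <- diffusion_table()
#' tab <- set_difc(tab, "AMPAR", 0.45)
#' tab <- set_surface_difc(tab, "psd", "AMPAR", 0.45e-5)
#' lookup_difc(tab, "AMPAR", "surface", "psd")   # override
#' lookup_difc(tab, "AMPAR", "surface", "esm")   # falls back to default
#' @export
diffusion_table <- function() {
  structure(list(default = list(), override = list()), class = "diffusion_table")
}

#' Set a default diffusion coefficient
#' @param table a [diffusion_table()].
#' @param species,state species identifier and state label.
#' @param D diffusion coefficient (um^2/s), >= 0.
#' @export
set_difc <- function(table, species, D, state = "surface") {
  if (D < 0) stop("diffusion coefficient must be >= 0")
  table$default[[.dt_key(species, state)]] <- D
  table
}

#' Set a per-surface diffusion override
#'
#' The override takes precedence over the species default on the named
#' surface only ("an exemption to the general diffusive behaviour of a
#' species for a specific surface"). The (species, state) pair must already
#' have a default.
#'
#' @inheritParams set_difc
#' @param surface surface name the override applies to.
#' @export
set_surface_difc <- function(table, surface, species, D, state = "surface") {
  if (D < 0) stop("diffusion coefficient must be >= 0")
  if (is.null(table$default[[.dt_key(species, state)]]))
    stop(sprintf("no default difc declared for species '%s' (state '%s')",
                 species, state))
  table$override[[paste(.dt_key(species, state), surface, sep = "\r")]] <- D
  table
}

#' Look up the diffusion coefficient for a species on a surface
#'
#' Returns the per-surface override when present, otherwise the default.
#'
#' @inheritParams set_surface_difc
#' @return diffusion coefficient (um^2/s).
#' @export
lookup_difc <- function(table, species, state = "surface", surface) {
  key <- .dt_key(species, state)
  if (is.null(table$default[[key]]))
    stop(sprintf("undeclared species '%s' (state '%s')", species, state))
  ov <- table$override[[paste(key, surface, sep = "\r")]]
  if (!is.null(ov)) ov else table$default[[key]]
}

# resolved species x surface matrix for the engine
.resolve_difc_matrix <- function(table, keys, surfaces) {
  D <- matrix(0, length(keys), length(surfaces))
  for (i in seq_along(keys)) {
    sp <- keys[[i]]
    for (s in seq_along(surfaces))
      D[i, s] <- lookup_difc(table, sp$species, sp$state, surfaces[s])
  }
  D
}

#' Create a step sampler
#'
#' Thin handle bundling the timestep; randomness comes from R's global RNG,
#' so `set.seed()` gives reproducible step sequences.
#'
#' @param dt timestep (s), > 0.
#' @export
step_sampler <- function(dt) {
  if (!(dt > 0)) stop("dt must be > 0")
  structure(list(dt = dt), class = "step_sampler")
}

#' Sample tangent-plane Brownian displacements
#'
#' Each component is an independent zero-mean Gaussian with standard
#' deviation sqrt(2 D dt).
#'
#' @param sampler a [step_sampler()].
#' @param D diffusion coefficient (um^2/s).
#' @param n number of displacements.
#' @return length-2 vector for `n = 1`, otherwise an n x 2 matrix (um).
#' @export
sample_step <- function(sampler, D, n = 1) {
  if (D < 0) stop("diffusion coefficient must be >= 0")
  sd <- sqrt(2 * D * sampler$dt)
  m <- matrix(rnorm(2 * n, 0, sd), n, 2)
  if (n == 1) as.numeric(m) else m
}

#' Diffuse a molecule for one timestep
#'
#' The whole step uses the diffusion coefficient of the surface the molecule
#' occupies at the START of the step; if the step crosses onto another
#' surface, the new coefficient takes effect only from the next step.
#'
#' @param pos a [surface_position()].
#' @param species,state species identifier and state label.
#' @param table a [diffusion_table()].
#' @param mesh a mesh.
#' @param sampler a [step_sampler()].
#' @param confine reflect at surface-to-surface edges.
#' @param max_crossings passed to [propagate()].
#' @return the new [surface_position()].
#' @export
diffuse_molecule <- function(pos, species, state = "surface", table, mesh,
                             sampler, confine = FALSE, max_crossings = 1000) {
  surf <- mesh$surfaces[mesh$surf[pos$panel]]
  D <- lookup_difc(table, species, state, surf)
  step <- sample_step(sampler, D)
  propagate(pos, step, mesh, max_crossings = max_crossings,
            confine = confine)$position
}
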