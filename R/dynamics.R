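# Implicit-solvent Brownian propagation under the production schedules.

#' Integrator configuration
#'
#' Time step and evaluation cadences for the Brownian propagator.  Defaults
#' are the production schedule: 125 fs step, nonbonded list rebuild every
#' 6 ps, medium-range evaluation every 1 ps, diffusion-tensor update every
#' 24 ps, snapshots every 100 ps.  Binding-event monitors are checked at the
#' list-rebuild cadence (6 ps).  All intervals must be integer multiples of
#' the time step.
#'
#' @param timestep_fs integration time step, fs.
#' @param list_interval_ps nonbonded-list rebuild interval, ps.
#' @param medium_interval_ps medium-range evaluation interval, ps.
#' @param tensor_interval_ps diffusion-tensor update interval, ps
#'   (hydrodynamic tensor mode only).
#' @param snapshot_interval_ps trajectory snapshot interval, ps.
#' @param check_interval_ps event-monitor check interval, ps.
#' @param hydrodynamics \code{"free-draining"} (default; diagonal Stokes
#'   mobilities) or \code{"tensor"} (pairwise Rotne-Prager-Yamakawa mobility).
#' @param noise_scheme correlated-noise factorization in tensor mode:
#'   \code{"cholesky"} (exact) or \code{"tea"} (first-order truncated
#'   expansion with variance-corrected diagonal).
#' @param tea_beta off-diagonal weight of the truncated expansion.
#' @param max_time_ns default trajectory length bound, ns.
#' @param pairlist_skin_A margin added to the pair cutoffs at list build so
#'   the lists stay valid between rebuilds.
#' @param max_step_A per-step displacement clamp, A.  About 15 times the
#'   thermal step, so it never engages in equilibrated dynamics; it lets
#'   the integrator relax starting structures in which a re-enabled
#'   attractive well overlaps an occupied position.  Set to \code{Inf} to
#'   disable, in which case displacements above 10 A raise an instability
#'   error.
#' @return An object of class \code{bd_config}.
#' @export
bd_config <- function(timestep_fs = 125, list_interval_ps = 6,
                      medium_interval_ps = 1, tensor_interval_ps = 24,
                      snapshot_interval_ps = 100, check_interval_ps = 6,
                      hydrodynamics = c("free-draining", "tensor"),
                      noise_scheme = c("cholesky", "tea"), tea_beta = 0.5,
                      max_time_ns = 1000, pairlist_skin_A = 2,
                      max_step_A = 1.5) {
  hydrodynamics <- match.arg(hydrodynamics)
  noise_scheme <- match.arg(noise_scheme)
  dt_ps <- timestep_fs / 1000
  iv <- c(list = list_interval_ps, medium = medium_interval_ps,
          tensor = tensor_interval_ps, snapshot = snapshot_interval_ps,
          check = check_interval_ps)
  steps <- iv / dt_ps
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("all intervals must be integer multiples of the time step")
  structure(list(timestep_fs = timestep_fs, dt_ps = dt_ps,
                 list_interval_ps = list_interval_ps,
                 medium_interval_ps = medium_interval_ps,
                 tensor_interval_ps = tensor_interval_ps,
                 snapshot_interval_ps = snapshot_interval_ps,
                 check_interval_ps = check_interval_ps,
                 hydrodynamics = hydrodynamics, noise_scheme = noise_scheme,
                 tea_beta = tea_beta, max_time_ns = max_time_ns,
                 pairlist_skin_A = pairlist_skin_A,
                 max_step_A = max_step_A,
                 steps = round(steps)), class = "bd_config")
}

#' Mobility model
#'
#' Free-draining mode returns the diagonal Stokes-Einstein mobilities
#' \code{D_i = kBT/(6 pi eta a_i)}; tensor mode returns the symmetric
#' positive-definite pairwise Rotne-Prager-Yamakawa mobility matrix
#' (3N x 3N) with overlap regularization.
#'
#' @param coords N x 3 coordinates (A); required in tensor mode.
#' @param radii per-bead hydrodynamic radii (A).
#' @param mode \code{"free-draining"} or \code{"tensor"}.
#' @param temperature K.
#' @param viscosity Pa s.
#' @return List with \code{mode} and either \code{D} (length-N vector,
#'   A^2/ps) or \code{tensor} (3N x 3N matrix, A^2/ps).
#' @export
diffusion_model <- function(coords = NULL, radii,
                            mode = c("free-draining", "tensor"),
                            temperature = 298, viscosity = 8.9e-4) {
  mode <- match.arg(mode)
  if (mode == "free-draining") {
    list(mode = mode, D = stokes_diffusion(radii, temperature, viscosity))
  } else {
    if (is.null(coords)) stop("tensor mode requires coordinates")
    kfac <- 1.380649e-23 * temperature / viscosity * 1e18  # -> A^2/ps scale
    list(mode = mode,
         tensor = .cgp_rpy_tensor(as.matrix(coords), radii, kfac))
  }
}

# Noise factor B with B B^T ~ D (exact Cholesky, or truncated expansion).
noise_factor <- function(D, scheme = c("cholesky", "tea"), beta = 0.5) {
  scheme <- match.arg(scheme)
  .cgp_noise_factor(D, scheme, beta)
}

#' Propagate a system with Brownian dynamics
#'
#' Overdamped (inertialess) Langevin propagation
#' \code{dx = (dt/kBT) D F + sqrt(2 dt) B xi} with the production pair
#' schedule: short-range interactions every step, medium-range at their
#' cadence with held forces in between, electrostatics without cutoff.
#' Binding-event monitors (P-site trigger groups) are evaluated at the check
#' cadence; the run terminates when all trigger contacts of a terminating
#' group are simultaneously formed, or at the time bound.  Trajectories are
#' bitwise reproducible from the seed.
#'
#' @param topology a \code{cg_topology}.
#' @param ff a \code{go_forcefield}.
#' @param config a \code{bd_config}.
#' @param duration_ns simulated time bound, ns.
#' @param seed integer RNG seed.
#' @param coords optional starting coordinates (defaults to the topology
#'   reference).
#' @param monitors list of trigger-group monitors; defaults to the
#'   topology's enabled P-site groups (productive groups terminate).
#'   \code{FALSE} disables monitoring.
#' @param contact_gamma a trigger contact counts as formed when the pair
#'   distance is at most \code{contact_gamma * sigma_ij}.
#' @param store_coords record snapshot coordinates.
#' @param record_monitors record per-group formed-contact counts at the
#'   snapshot cadence.
#' @param record_energy record total energy at the snapshot cadence.
#' @param distance_pairs optional 2-column matrix of bead index pairs whose
#'   distances are recorded at the snapshot cadence.
#' @return A \code{bd_trajectory}: final coordinates, frame times (ns),
#'   optional frames/monitor counts/distances, and a \code{termination}
#'   record (reason \code{"event"}, \code{"max-time"} or \code{"nan"}; for
#'   events also the fired site, chain, cis flag and elapsed time).
#' @export
run_dynamics <- function(topology, ff, config = bd_config(),
                         duration_ns = config$max_time_ns, seed = 1,
                         coords = topology$coords, monitors = NULL,
                         contact_gamma = 1.2, store_coords = FALSE,
                         record_monitors = FALSE, record_energy = FALSE,
                         distance_pairs = NULL) {
  if (is.null(monitors)) monitors <- psite_monitors(topology, contact_gamma)
  if (isFALSE(monitors)) monitors <- list()
  nsteps <- round(duration_ns * 1000 / config$dt_ps)
  if (nsteps < 1) stop("duration shorter than one time step")
  D <- stokes_diffusion(topology$beads$radius, ff$temperature, ff$viscosity)
  kfac <- 1.380649e-23 * ff$temperature / ff$viscosity * 1e18
  opts <- list(dt_ps = config$dt_ps, nsteps = as.double(nsteps),
               list_every = config$steps[["list"]],
               medium_every = config$steps[["medium"]],
               check_every = config$steps[["check"]],
               snap_every = config$steps[["snapshot"]],
               store_coords = store_coords,
               record_monitors = record_monitors,
               record_energy = record_energy,
               max_disp = 10,
               max_step = if (is.finite(config$max_step_A))
                 config$max_step_A else -1,
               tensor_mode = config$hydrodynamics == "tensor",
               tensor_every = config$steps[["tensor"]],
               noise_scheme = config$noise_scheme,
               tea_beta = config$tea_beta,
               kBT_over_eta = kfac,
               skin = config$pairlist_skin_A)
  dp <- if (is.null(distance_pairs)) matrix(integer(), 0, 2)
        else as.matrix(distance_pairs)
  storage.mode(dp) <- "integer"
  res <- .cgp_run_bd(pack_topology(topology, ff), as.matrix(coords),
                     ff_vector(ff), D, opts, unname(monitors), dp,
                     as.double(seed))
  term <- list(reason = c("max-time", "event", "nan")[res$status + 1],
               time_ns = res$time_ps / 1000, seed = seed)
  if (res$status == 1) {
    g <- monitors[[res$event_group]]
    term$site <- g$site; term$chain <- g$chain; term$cis <- g$cis
  }
  out <- list(final = res$coords, times_ns = res$frame_times / 1000,
              termination = term, seed = seed, n_capped = res$n_capped)
  if (store_coords) {
    n <- nrow(res$coords)
    nf <- length(res$frame_times)
    out$frames <- lapply(seq_len(nf), function(k)
      matrix(res$frames[k, ], n, 3, byrow = TRUE))
  }
  if (record_monitors) {
    out$monitor_counts <- res$monitor_counts
    colnames(out$monitor_counts) <-
      vapply(monitors, function(m) paste0(m$site, "/", m$role %||% ""),
             character(1))
  }
  if (!is.null(res$distances)) out$distances <- res$distances
  if (record_energy) out$energy <- res$energy
  class(out) <- "bd_trajectory"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("bd_trajectory: %.4g ns simulated, terminated by %s\n",
              x$termination$time_ns, x$termination$reason))
  if (x$termination$reason == "event")
    cat(sprintf("  event: P-site %s (chain %s, %s)\n", x$termination$site,
                x$termination$chain,
                if (isTRUE(x$termination$cis)) "cis" else "trans"))
  invisible(x)
}
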