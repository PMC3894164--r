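# Force-field parameter container and energy/force evaluation.

KB_KCAL <- 0.0019872041      # Boltzmann constant, kcal/mol/K
COULOMB_KCAL <- 332.0637     # e^2/(4 pi eps0), kcal*A/mol

#' Go-model force field parameters
#'
#' Bundles every energy-term constant of the coarse-grained energetic model:
#' harmonic bond/angle constants, dihedral barrier heights, the native-contact
#' well depth, the generic short-range repulsion, Debye-Hueckel screened
#' electrostatics, and the membrane-slab restraints.  Defaults are the
#' production parameterization of the receptor model: bonds 20 kcal/mol/A^2,
#' angles 10 kcal/mol/rad^2, dihedral barriers 0.5/0.25 kcal/mol, contact and
#' repulsive epsilon 0.6 kcal/mol, sigma_vdw 4 A, ionic strength 0.15 M,
#' dielectric 78.4, membrane planes at z = +/-16.5 A with 5.0 kcal/mol/A^2
#' restraint and wall constants.
#'
#' The Debye screening length is always derived from the ionic strength and
#' temperature (about 7.9 A at 0.15 M, 298 K); it cannot be set independently.
#'
#' Harmonic terms are evaluated as \code{k * (delta)^2} (no factor 1/2), so
#' the printed constants act exactly as written.
#'
#' @param k_bond harmonic bond constant, kcal/mol/A^2.
#' @param k_angle harmonic angle constant, kcal/mol/rad^2.
#' @param V1,V3 dihedral barrier heights, kcal/mol.
#' @param epsilon native-contact well depth, kcal/mol.
#' @param sigma_vdw repulsive diameter, A.
#' @param eps_rep repulsive prefactor, kcal/mol.
#' @param ionic_strength molar ionic strength of the implicit solvent.
#' @param dielectric relative solvent dielectric constant.
#' @param temperature simulation temperature, K.
#' @param viscosity solvent viscosity, Pa s (water at 25 C by default).
#' @param z_wall membrane half-separation, A (planes 2*z_wall apart).
#' @param k_restraint transmembrane z-restraint constant, kcal/mol/A^2.
#' @param k_wall half-harmonic wall constant, kcal/mol/A^2.
#' @param r_short short-range pair cutoff, A (evaluated every step).
#' @param r_medium medium-range pair cutoff, A (evaluated at the 1 ps cadence).
#' @param contact_form attractive-well functional form: \code{"12-10-6"}
#'   (default; minimum -epsilon at sigma) or \code{"12-10"}.
#' @return An object of class \code{go_forcefield}.
#' @examples
#' ff <- go_forcefield()
#' ff$lambda_debye   # ~7.9 A at 0.15 M, 298 K
#' @export
go_forcefield <- function(k_bond = 20, k_angle = 10, V1 = 0.5, V3 = 0.25,
                          epsilon = 0.6, sigma_vdw = 4, eps_rep = 0.6,
                          ionic_strength = 0.15, dielectric = 78.4,
                          temperature = 298, viscosity = 8.9e-4,
                          z_wall = 16.5, k_restraint = 5.0, k_wall = 5.0,
                          r_short = 12.5, r_medium = 25,
                          contact_form = c("12-10-6", "12-10")) {
  contact_form <- match.arg(contact_form)
  vals <- c(k_bond, k_angle, V1, V3, epsilon, sigma_vdw, eps_rep,
            ionic_strength, dielectric, temperature, viscosity,
            z_wall, k_restraint, k_wall, r_short, r_medium)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all force-field constants must be positive and finite")
  if (r_medium <= r_short) stop("r_medium must exceed r_short")
  ff <- list(
    k_bond = k_bond, k_angle = k_angle, V1 = V1, V3 = V3,
    epsilon = epsilon, sigma_vdw = sigma_vdw, eps_rep = eps_rep,
    ionic_strength = ionic_strength, dielectric = dielectric,
    temperature = temperature, viscosity = viscosity,
    z_wall = z_wall, k_restraint = k_restraint, k_wall = k_wall,
    r_short = r_short, r_medium = r_medium,
    contact_form = contact_form,
    kBT = KB_KCAL * temperature,
    lambda_debye = debye_length(ionic_strength, temperature, dielectric))
  class(ff) <- "go_forcefield"
  ff
}

#' @export
print.go_forcefield <- function(x, ...) {
  cat("Go-model force field\n")
  cat(sprintf("  bonds %g kcal/mol/A^2, angles %g kcal/mol/rad^2, V1/V3 %g/%g\n",
              x$k_bond, x$k_angle, x$V1, x$V3))
  cat(sprintf("  contact eps %g kcal/mol (%s well), repulsion eps %g at sigma %g A\n",
              x$epsilon, x$contact_form, x$eps_rep, x$sigma_vdw))
  cat(sprintf("  electrostatics: I = %g M, eps_s = %g, lambda_D = %.2f A, T = %g K\n",
              x$ionic_strength, x$dielectric, x$lambda_debye, x$temperature))
  cat(sprintf("  membrane: walls at +/-%g A, k_restraint = k_wall = %g kcal/mol/A^2\n",
              x$z_wall, x$k_restraint))
  invisible(x)
}

#' Debye screening length
#'
#' Screening length of a symmetric electrolyte from molar ionic strength,
#' temperature and solvent dielectric.
#'
#' @param ionic_strength molar ionic strength (M).
#' @param temperature temperature (K).
#' @param dielectric relative dielectric constant.
#' @return Screening length in Angstrom.
#' @export
debye_length <- function(ionic_strength, temperature = 298, dielectric = 78.4) {
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  e <- 1.602176634e-19; NA_ <- 6.02214076e23
  lam <- sqrt(eps0 * dielectric * kB * temperature /
              (2 * NA_ * e^2 * ionic_strength * 1000))
  lam * 1e10
}

#' Stokes-Einstein diffusion coefficient
#'
#' Free-draining translational diffusion coefficient of a sphere.
#'
#' @param radius hydrodynamic radius, A.
#' @param temperature temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @return Diffusion coefficient in A^2/ps.
#' @export
stokes_diffusion <- function(radius, temperature = 298, viscosity = 8.9e-4) {
  kB <- 1.380649e-23
  D_m2s <- kB * temperature / (6 * pi * viscosity * radius * 1e-10)
  D_m2s * 1e8
}

# ff vector handed to the C++ core
ff_vector <- function(ff) {
  c(k_bond = ff$k_bond, k_angle = ff$k_angle, V1 = ff$V1, V3 = ff$V3,
    eps_rep = ff$eps_rep, sigma_vdw = ff$sigma_vdw,
    eps_s = ff$dielectric, lambda_D = ff$lambda_debye, coul = COULOMB_KCAL,
    kBT = ff$kBT, z_wall = ff$z_wall, k_restraint = ff$k_restraint,
    k_wall = ff$k_wall, r_short = ff$r_short, r_medium = ff$r_medium)
}

# Pack a cg_topology into plain vectors for the C++ core.  Dihedral phases
# are chosen so the native dihedral is the minimum: phi1 = phi_native + pi,
# phi3 = 3*phi_native + pi.  Only active contacts of enabled groups are sent.
pack_topology <- function(top, ff) {
  b <- top$beads
  con <- active_contacts(top)
  form <- if (ff$contact_form == "12-10-6") 0L else 1L
  list(
    charge = as.numeric(b$charge),
    radius = as.numeric(b$radius),
    z0 = ifelse(is.na(b$z0), 0, as.numeric(b$z0)),
    chain = as.integer(factor(b$chain)),
    resno = as.integer(b$resno),
    kind = as.integer(b$kind == "nucleotide"),
    complex_id = ifelse(is.na(b$complex_id), -1L, as.integer(b$complex_id)),
    side = as.integer(b$side),
    is_tm = as.integer(b$is_tm),
    bonds = cbind(as.integer(top$bonds$i) - 1L, as.integer(top$bonds$j) - 1L),
    bond_req = as.numeric(top$bonds$r_eq),
    angles = cbind(as.integer(top$angles$i) - 1L, as.integer(top$angles$j) - 1L,
                   as.integer(top$angles$k) - 1L),
    angle_eq = as.numeric(top$angles$theta_eq),
    dihedrals = cbind(as.integer(top$dihedrals$i) - 1L,
                      as.integer(top$dihedrals$j) - 1L,
                      as.integer(top$dihedrals$k) - 1L,
                      as.integer(top$dihedrals$l) - 1L),
    dih_phi1 = as.numeric(top$dihedrals$phi_native) + pi,
    dih_phi3 = 3 * as.numeric(top$dihedrals$phi_native) + pi,
    contacts = cbind(as.integer(con$i) - 1L, as.integer(con$j) - 1L),
    contact_sigma = as.numeric(con$sigma),
    contact_eps = as.numeric(con$eps),
    contact_form = rep(form, nrow(con)))
}

energy_terms_ <- function(top, ff, coords, which) {
  sel <- c("bond", "angle", "dihedral", "contact", "repulsive",
           "electrostatic", "membrane") %in% which
  res <- .cgp_energy(pack_topology(top, ff), coords, ff_vector(ff), sel)
  list(energy = res$total, terms = res$terms, forces = res$forces)
}

#' Bonded energy and forces
#'
#' Harmonic bond and angle terms plus the two-component cosine dihedral term,
#' with equilibrium values taken from the reference structure.  Forces are the
#' exact negative gradient.
#'
#' @param topology a \code{cg_topology}.
#' @param ff a \code{go_forcefield}.
#' @param coords bead coordinates (N x 3 matrix, A); defaults to the
#'   topology's reference coordinates.
#' @return List with \code{energy} (kcal/mol), \code{terms} breakdown, and
#'   \code{forces} (N x 3, kcal/mol/A).
#' @export
bonded_energy <- function(topology, ff, coords = topology$coords)
  energy_terms_(topology, ff, coords, c("bond", "angle", "dihedral"))

#' Native-contact attraction energy and forces
#'
#' Go-type short-range attraction for native-contact pairs.  With the default
#' 12-10-6 form the well minimum is exactly \code{-epsilon} at the native
#' pseudo-atom separation \code{sigma_ij}.
#'
#' @inheritParams bonded_energy
#' @export
contact_energy <- function(topology, ff, coords = topology$coords)
  energy_terms_(topology, ff, coords, "contact")

#' Generic short-range repulsion energy and forces
#'
#' Strictly repulsive \code{eps*(sigma_vdw/r)^12} term between non-bonded
#' pairs that are not native contacts.
#'
#' @inheritParams bonded_energy
#' @export
repulsive_energy <- function(topology, ff, coords = topology$coords)
  energy_terms_(topology, ff, coords, "repulsive")

#' Screened electrostatic energy and forces
#'
#' Debye-Hueckel potential between charged non-bonded beads; no distance
#' cutoff is applied.
#'
#' @inheritParams bonded_energy
#' @export
electrostatic_energy <- function(topology, ff, coords = topology$coords)
  energy_terms_(topology, ff, coords, "electrostatic")

#' Membrane restraint energy and forces
#'
#' Transmembrane beads are harmonically restrained to their reference z;
#' extracellular beads feel a half-harmonic wall below \code{+z_wall} and
#' intracellular (and nucleotide) beads one above \code{-z_wall}.
#'
#' @inheritParams bonded_energy
#' @export
membrane_energy <- function(topology, ff, coords = topology$coords)
  energy_terms_(topology, ff, coords, "membrane")

#' Total energy with per-term breakdown
#'
#' Evaluates every term of the energetic model exactly (no pair-schedule
#' caching) and returns the per-term breakdown, which sums to the total.
#'
#' @inheritParams bonded_energy
#' @param schedule optional \code{pair_schedule}; accepted for interface
#'   symmetry with the propagator, which caches medium-range forces.  The
#'   energies returned here are always freshly evaluated.
#' @export
total_energy <- function(topology, ff, coords = topology$coords,
                         schedule = NULL) {
  energy_terms_(topology, ff, coords,
                c("bond", "angle", "dihedral", "contact", "repulsive",
                  "electrostatic", "membrane"))
}

#' Nonbonded pair schedule
#'
#' Classifies all non-bonded pairs at the given coordinates into the
#' short-range list (within \code{r_short}, evaluated every step), the
#' medium-range list (\code{r_short} to \code{r_medium}, evaluated at the
#' 1 ps cadence and held in between) and the unrestricted electrostatic far
#' list (charged pairs beyond \code{r_medium}; electrostatics has no cutoff).
#'
#' @inheritParams bonded_energy
#' @return A \code{pair_schedule}: matrices \code{short}, \code{medium},
#'   \code{electrostatic_far} of 1-based bead index pairs plus the rebuild and
#'   evaluation cadences (ps).
#' @export
build_schedule <- function(topology, ff, coords = topology$coords) {
  cls <- .cgp_pair_classes(pack_topology(topology, ff), coords, ff_vector(ff))
  structure(list(short = cls$short, medium = cls$medium,
                 electrostatic_far = cls$electrostatic_far,
                 rebuild_interval_ps = 6, medium_interval_ps = 1),
            class = "pair_schedule")
}
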