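# The coarse-grained system container: beads, bonded terms, native contacts,
# P-site trigger groups, membrane assignment.

#' Construct a pseudo-atom topology
#'
#' Low-level constructor for the coarse-grained system: one bead per protein
#' residue (radius 5.3 A) plus nine beads per bound nucleotide complex
#' (radius 3.5 A), sequence bonds/angles/dihedrals with equilibrium values
#' from the reference coordinates, native contacts, and P-site contact
#' groups.  Most users build topologies with \code{\link{coarse_grain}} or
#' \code{\link{make_toy_dimer}} rather than calling this directly.
#'
#' @param coords N x 3 reference coordinates (A).
#' @param beads data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{kind} ("residue"/"nucleotide"), \code{region},
#'   \code{complex_id}, \code{charge}, \code{radius}, \code{is_tm},
#'   \code{side} (+1 extracellular, -1 intracellular, 0 in-membrane) and
#'   \code{z0} (TM restraint reference).
#' @param bonds,angles,dihedrals bonded term tables (1-based bead indices
#'   with equilibrium geometry columns \code{r_eq}, \code{theta_eq},
#'   \code{phi_native}).
#' @param contacts native-contact table: \code{i}, \code{j}, \code{sigma},
#'   \code{eps}, \code{tag} ("fold", "interface", "nucleotide-site" or
#'   "psite:<id>"), \code{active}.
#' @param psite_groups list of P-site contact groups (see
#'   \code{\link{build_psite_groups}}).
#' @param catalytic optional list describing catalytic-site anchors
#'   (gamma-phosphate bead, catalytic aspartate bead, receiver chain).
#' @return An object of class \code{cg_topology}.
#' @export
cg_topology <- function(coords, beads,
                        bonds = empty_bonds(), angles = empty_angles(),
                        dihedrals = empty_dihedrals(),
                        contacts = empty_contacts(),
                        psite_groups = list(), catalytic = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, nrow(coords) == nrow(beads))
  if (any(!is.finite(coords))) stop("reference coordinates must be finite")
  if (is.null(beads$z0)) beads$z0 <- NA_real_
  if (is.null(beads$complex_id)) beads$complex_id <- NA_integer_
  if (!is.null(contacts) && nrow(contacts) > 0) {
    if (any(contacts$sigma <= 0)) stop("contact sigma must be positive")
    key <- paste(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
    if (anyDuplicated(key)) stop("duplicate native-contact pairs")
  }
  if (is.null(contacts$active)) contacts$active <- TRUE
  structure(list(coords = coords, beads = beads, bonds = bonds,
                 angles = angles, dihedrals = dihedrals, contacts = contacts,
                 psite_groups = psite_groups, catalytic = catalytic),
            class = "cg_topology")
}

empty_bonds <- function()
  data.frame(i = integer(), j = integer(), r_eq = numeric())
empty_angles <- function()
  data.frame(i = integer(), j = integer(), k = integer(), theta_eq = numeric())
empty_dihedrals <- function()
  data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
             phi_native = numeric())
empty_contacts <- function()
  data.frame(i = integer(), j = integer(), sigma = numeric(), eps = numeric(),
             tag = character(), active = logical())

#' @export
print.cg_topology <- function(x, ...) {
  b <- x$beads
  cat(sprintf("cg_topology: %d beads (%d residue, %d nucleotide) in %d chain(s)\n",
              nrow(b), sum(b$kind == "residue"), sum(b$kind == "nucleotide"),
              length(unique(b$chain))))
  cat(sprintf("  %d bonds, %d angles, %d dihedrals, %d native contacts (%d active)\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$contacts), sum(x$contacts$active)))
  if (length(x$psite_groups)) {
    en <- vapply(x$psite_groups, function(g) isTRUE(g$enabled), logical(1))
    cat(sprintf("  %d P-site contact groups (%d enabled)\n",
                length(x$psite_groups), sum(en)))
  }
  if (any(b$is_tm))
    cat(sprintf("  %d transmembrane beads restrained in the membrane slab\n",
                sum(b$is_tm)))
  invisible(x)
}

# Contacts that are currently in force: active rows whose psite tag (if any)
# belongs to an enabled group.
active_contacts <- function(top) {
  con <- top$contacts
  if (nrow(con) == 0) return(con)
  keep <- con$active
  if (length(top$psite_groups)) {
    disabled <- vapply(top$psite_groups,
                       function(g) if (!isTRUE(g$enabled)) g$tag else NA_character_,
                       character(1))
    disabled <- disabled[!is.na(disabled)]
    if (length(disabled)) keep <- keep & !(con$tag %in% disabled)
  }
  con[keep, , drop = FALSE]
}

#' Total charge of the system
#' @param topology a \code{cg_topology}.
#' @return Net charge in elementary units.
#' @export
total_charge <- function(topology) sum(topology$beads$charge)

#' Remove all P-site attractive terms
#'
#' Disables every P-site contact group (productive and mirror), which
#' precludes stable P-site/active-site interactions; used to generate
#' conformation-randomization ensembles.  The contact template is retained so
#' \code{\link{restore_psite_attractions}} recovers the original native
#' contact set exactly.
#'
#' @param topology a \code{cg_topology}.
#' @return Modified topology.
#' @export
strip_psite_attractions <- function(topology) {
  topology$psite_groups <- lapply(topology$psite_groups, function(g) {
    g$enabled <- FALSE
    g
  })
  topology
}

#' Re-enable P-site attractive terms
#'
#' Inverse of \code{\link{strip_psite_attractions}}.  Groups whose contacts
#' were permanently removed by \code{\link{mimic_phosphorylation}} stay
#' disabled.
#'
#' @param topology a \code{cg_topology}.
#' @return Modified topology.
#' @export
restore_psite_attractions <- function(topology) {
  topology$psite_groups <- lapply(topology$psite_groups, function(g) {
    if (!isTRUE(g$removed)) g$enabled <- TRUE
    g
  })
  topology
}

# Find a P-site group by site id (e.g. "992A"), optionally by role.
find_psite_group <- function(top, site, role = NULL) {
  hit <- which(vapply(top$psite_groups, function(g) {
    g$site == site && (is.null(role) || g$role == role)
  }, logical(1)))
  if (!length(hit)) stop("unknown P-site: ", site)
  hit
}

# Monitor descriptors for the C++ propagator: productive groups terminate,
# mirror groups are observed only.
psite_monitors <- function(top, gamma = 1.2, only_enabled = TRUE,
                           force_nonterminating = FALSE) {
  groups <- if (only_enabled)
    Filter(function(g) isTRUE(g$enabled), top$psite_groups)
  else top$psite_groups
  lapply(groups, function(g) {
    list(i = g$pairs$i, j = g$pairs$j, sigma = g$pairs$sigma,
         gamma = gamma, trigger = g$trigger,
         terminating = identical(g$role, "productive") &&
           !force_nonterminating,
         site = g$site, chain = g$chain, cis = g$cis, role = g$role)
  })
}
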