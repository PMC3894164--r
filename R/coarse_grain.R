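# All-atom -> pseudo-atom conversion, native-contact detection, charge
# assignment, and P-site contact-group construction.

RESIDUE_RADIUS <- 5.3      # hydrodynamic radius of residue beads, A
NUCLEOTIDE_RADIUS <- 3.5   # finer-grained nucleotide-complex beads, A

# pseudo-atom centers of one nucleotide complex (alternate PDB spellings)
NUC_BEAD_ATOMS <- list(C2 = "C2", C6 = "C6", N9 = "N9",
                       C4p = c("C4'", "C4*"),
                       P1 = c("P1", "PA"), P2 = c("P2", "PB"),
                       P3 = c("P3", "PG"))

#' Coarse-grain an annotated structure
#'
#' One bead per protein residue, centered on the C-alpha (radius 5.3 A);
#' nine beads per nucleotide complex (adenine C2/C6/N9, ribose C4', the
#' three phosphorus atoms, and two Mg ions; radius 3.5 A).  Sequence
#' neighbours are bonded, with angles over consecutive triples and dihedrals
#' over quadruples; equilibrium values are taken from the reference
#' structure.  Nucleotide-complex beads are fully interconnected by harmonic
#' bonds (36 per complex), which fixes the complex geometry, so no separate
#' angle terms are enumerated for them.
#'
#' Membrane sides: transmembrane residues become z-restrained beads
#' (reference z recorded as z0); extracellular/ligand residues are assigned
#' to the outer side of the slab, intracellular and nucleotide beads to the
#' inner side; structured/modeled residues fall back to the sign of their
#' reference z.
#'
#' @param structure an \code{annotated_structure}.
#' @return A \code{cg_topology} (uncharged; see \code{\link{assign_charges}}).
#' @export
coarse_grain <- function(structure) {
  at <- structure$atoms
  reg <- structure$regions
  key <- paste(at$chain, at$resno)
  rkey <- paste(reg$chain, reg$resno)
  at$region <- reg$region[match(key, rkey)]

  beads <- NULL
  coords <- NULL
  complex_counter <- 0L
  for (ch in unique(reg$chain)) {
    rch <- reg[reg$chain == ch, ]
    rch <- rch[order(rch$resno), ]
    nuc <- rch$region == "nucleotide-complex"
    # protein residue beads
    for (ri in which(!nuc)) {
      rs <- rch$resno[ri]
      ra <- at[at$chain == ch & at$resno == rs, ]
      ca <- ra[ra$elety == "CA", ]
      if (nrow(ca) != 1)
        stop("residue ", ch, ":", rs, " has no (unique) C-alpha atom")
      beads <- rbind(beads, data.frame(
        chain = ch, resno = rs, resname = ra$resid[1], kind = "residue",
        region = rch$region[ri], complex_id = NA_integer_, charge = 0,
        radius = RESIDUE_RADIUS, stringsAsFactors = FALSE))
      coords <- rbind(coords, c(ca$x, ca$y, ca$z))
    }
    # nucleotide complexes: one per contiguous run of labeled residues
    if (any(nuc)) {
      runs <- split(rch$resno[nuc], cumsum(c(1, diff(which(nuc)) != 1)))
      for (rr in runs) {
        complex_counter <- complex_counter + 1L
        ra <- at[at$chain == ch & at$resno %in% rr, ]
        for (nm in names(NUC_BEAD_ATOMS)) {
          hit <- ra[ra$elety %in% NUC_BEAD_ATOMS[[nm]], ]
          if (nrow(hit) < 1)
            stop("nucleotide complex in chain ", ch, " lacks atom ", nm)
          hit <- hit[1, ]
          beads <- rbind(beads, data.frame(
            chain = ch, resno = hit$resno, resname = nm, kind = "nucleotide",
            region = "nucleotide-complex", complex_id = complex_counter,
            charge = 0, radius = NUCLEOTIDE_RADIUS, stringsAsFactors = FALSE))
          coords <- rbind(coords, c(hit$x, hit$y, hit$z))
        }
        mg <- ra[ra$elety %in% c("MG", "Mg"), ]
        if (nrow(mg) != 2)
          stop("nucleotide complex in chain ", ch, " needs two Mg atoms, found ",
               nrow(mg))
        for (q in 1:2) {
          beads <- rbind(beads, data.frame(
            chain = ch, resno = mg$resno[q], resname = "MG",
            kind = "nucleotide", region = "nucleotide-complex",
            complex_id = complex_counter, charge = 0,
            radius = NUCLEOTIDE_RADIUS, stringsAsFactors = FALSE))
          coords <- rbind(coords, c(mg$x[q], mg$y[q], mg$z[q]))
        }
      }
    }
  }
  rownames(beads) <- NULL
  beads$is_tm <- beads$region == "transmembrane"
  beads$side <- ifelse(beads$is_tm, 0L,
                ifelse(beads$region %in% c("extracellular", "ligand"), 1L,
                ifelse(beads$region %in% c("intracellular",
                                           "nucleotide-complex"), -1L,
                       ifelse(coords[, 3] > 0, 1L, -1L))))
  beads$z0 <- ifelse(beads$is_tm, coords[, 3], NA_real_)

  bonds <- empty_bonds(); angles <- empty_angles(); dih <- empty_dihedrals()
  for (ch in unique(beads$chain)) {
    idx <- which(beads$chain == ch & beads$kind == "residue")
    idx <- idx[order(beads$resno[idx])]
    if (length(idx) > 1) {
      consec <- diff(beads$resno[idx]) == 1
      for (q in which(consec)) {
        i <- idx[q]; j <- idx[q + 1]
        bonds <- rbind(bonds, data.frame(
          i = i, j = j, r_eq = sqrt(sum((coords[i, ] - coords[j, ])^2))))
      }
      if (length(idx) > 2) for (q in seq_len(length(idx) - 2)) {
        if (consec[q] && consec[q + 1]) {
          tri <- idx[q:(q + 2)]
          angles <- rbind(angles, data.frame(
            i = tri[1], j = tri[2], k = tri[3],
            theta_eq = angle_of(coords[tri[1], ], coords[tri[2], ],
                                coords[tri[3], ])))
        }
      }
      if (length(idx) > 3) for (q in seq_len(length(idx) - 3)) {
        if (consec[q] && consec[q + 1] && consec[q + 2]) {
          qu <- idx[q:(q + 3)]
          if (!dihedral_defined(coords[qu[1], ], coords[qu[2], ],
                                coords[qu[3], ], coords[qu[4], ])) next
          dih <- rbind(dih, data.frame(
            i = qu[1], j = qu[2], k = qu[3], l = qu[4],
            phi_native = dihedral_of(coords[qu[1], ], coords[qu[2], ],
                                     coords[qu[3], ], coords[qu[4], ])))
        }
      }
    }
  }
  if (any(beads$kind == "nucleotide")) {
    for (cid in unique(beads$complex_id[!is.na(beads$complex_id)])) {
      idx <- which(!is.na(beads$complex_id) & beads$complex_id == cid)
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b) {
          i <- idx[a]; j <- idx[b]
          bonds <- rbind(bonds, data.frame(
            i = i, j = j, r_eq = sqrt(sum((coords[i, ] - coords[j, ])^2))))
        }
      }
    }
  }
  cg_topology(coords, beads, bonds, angles, dih)
}

angle_of <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_of <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m <- pracma_cross(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

# A dihedral over collinear beads has no defined native angle; such terms
# are not created (matching the propagator's degeneracy switch).
dihedral_defined <- function(p1, p2, p3, p4, tol = 5e-3) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  sum(n1^2) >= tol * sum(b1^2) * sum(b2^2) &&
    sum(n2^2) >= tol * sum(b2^2) * sum(b3^2)
}

#' Detect native contacts from an all-atom reference
#'
#' A residue pair forms a native contact when any atom of one residue lies
#' within \code{cutoff} of any atom of the other in the reference structure,
#' both residues are eligible (by default: elements of known structure, i.e.
#' region \code{structured}, plus nucleotide complexes against structured
#' residues), and same-chain residue pairs are separated by at least three
#' residues.  The well minimum \code{sigma_ij} is the pseudo-atom
#' (C-alpha/bead center) separation in the reference.  Detection is all-atom
#' but the energy acts on the beads.
#'
#' @param structure an \code{annotated_structure}.
#' @param topology the matching \code{cg_topology} (defaults to
#'   \code{coarse_grain(structure)}).
#' @param cutoff all-atom contact distance cutoff, A.
#' @param eligible predicate on region labels.
#' @param eps well depth assigned to each contact, kcal/mol.
#' @return Native-contact data.frame (\code{i}, \code{j}, \code{sigma},
#'   \code{eps}, \code{tag}, \code{active}); tags are \code{"fold"} for
#'   residue/residue and \code{"nucleotide-site"} for complex/residue
#'   contacts.
#' @export
detect_native_contacts <- function(structure, topology = coarse_grain(structure),
                                   cutoff = 5.5,
                                   eligible = function(region)
                                     region %in% c("structured",
                                                   "nucleotide-complex"),
                                   eps = 0.6) {
  at <- structure$atoms
  reg <- structure$regions
  b <- topology$beads
  res_beads <- which(b$kind == "residue")
  elig <- eligible(reg$region[match(paste(b$chain, b$resno),
                                    paste(reg$chain, reg$resno))])
  # atom groups per residue bead
  groups <- lapply(res_beads, function(i)
    as.matrix(at[at$chain == b$chain[i] & at$resno == b$resno[i],
                 c("x", "y", "z")]))
  cent <- t(vapply(groups, colMeans, numeric(3)))
  spread <- vapply(seq_along(groups), function(k)
    if (nrow(groups[[k]])) sqrt(max(rowSums(sweep(groups[[k]], 2,
                                                  cent[k, ])^2))) else 0,
    numeric(1))
  out <- empty_contacts()
  nb <- length(res_beads)
  for (a in seq_len(nb)) {
    ia <- res_beads[a]
    if (!isTRUE(elig[ia])) next
    for (bq in seq_len(nb)) {
      if (bq <= a) next
      jb <- res_beads[bq]
      if (!isTRUE(elig[jb])) next
      if (b$chain[ia] == b$chain[jb] &&
          abs(b$resno[ia] - b$resno[jb]) < 3) next
      if (sqrt(sum((cent[a, ] - cent[bq, ])^2)) >
          cutoff + spread[a] + spread[bq]) next
      if (min_pair_dist(groups[[a]], groups[[bq]]) <= cutoff) {
        sg <- sqrt(sum((topology$coords[ia, ] - topology$coords[jb, ])^2))
        out <- rbind(out, data.frame(i = ia, j = jb, sigma = sg, eps = eps,
                                     tag = "fold", active = TRUE))
      }
    }
  }
  # nucleotide-complex beads vs structured residues
  nuc_beads <- which(b$kind == "nucleotide")
  for (i in nuc_beads) {
    pos <- topology$coords[i, , drop = FALSE]
    for (a in seq_len(nb)) {
      jb <- res_beads[a]
      if (!isTRUE(elig[jb])) next
      if (sqrt(sum((pos - cent[a, ])^2)) > cutoff + spread[a]) next
      if (min_pair_dist(pos, groups[[a]]) <= cutoff) {
        sg <- sqrt(sum((topology$coords[i, ] - topology$coords[jb, ])^2))
        out <- rbind(out, data.frame(i = min(i, jb), j = max(i, jb),
                                     sigma = sg, eps = eps,
                                     tag = "nucleotide-site", active = TRUE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Charges

AA_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1,
               D = -1, E = -1, K = 1, R = 1)
AA_KNOWN <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL",
              "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")

#' Assign charges to a topology
#'
#' Residues with a significant partial charge at the simulation pH carry
#' that charge: Asp/Glu -1, Lys/Arg +1, His by Henderson-Hasselbalch at the
#' given pH (pKa 6.0) and zeroed when the fractional charge falls below the
#' significance threshold (at pH 7.6 His carries ~0.024 and is zeroed).
#' Free chain termini optionally carry +1/-1.  Nucleotide complexes are
#' net-neutral: each phosphorus bead -4/3, each Mg +2.
#'
#' @param topology a \code{cg_topology}.
#' @param pH simulation pH.
#' @param significance minimum |q| retained.
#' @param charge_termini add +1/-1 to the first/last residue of each protein
#'   chain.
#' @param his_fractional keep the fractional His charge even below the
#'   significance threshold.
#' @return Topology with the \code{charge} column filled.
#' @export
assign_charges <- function(topology, pH = 7.6, significance = 0.1,
                           charge_termini = TRUE, his_fractional = FALSE) {
  b <- topology$beads
  q <- numeric(nrow(b))
  res <- b$kind == "residue"
  rn <- toupper(b$resname)
  q[res] <- ifelse(rn[res] %in% names(AA_CHARGE), AA_CHARGE[rn[res]], 0)
  his <- res & rn %in% c("HIS", "H")
  if (any(his)) {
    frac <- 10^(6.0 - pH) / (1 + 10^(6.0 - pH))
    q[his] <- if (his_fractional || frac >= significance) frac else 0
  }
  unknown <- res & !(rn %in% c(AA_KNOWN, names(AA_CHARGE)))
  if (any(unknown))
    warning("unknown residue name(s) assigned zero charge: ",
            paste(unique(rn[unknown]), collapse = ", "))
  if (charge_termini) {
    for (ch in unique(b$chain[res])) {
      idx <- which(res & b$chain == ch)
      q[idx[which.min(b$resno[idx])]] <-
        q[idx[which.min(b$resno[idx])]] + 1
      q[idx[which.max(b$resno[idx])]] <-
        q[idx[which.max(b$resno[idx])]] - 1
    }
  }
  nuc <- b$kind == "nucleotide"
  q[nuc & b$resname %in% c("P1", "P2", "P3")] <- -4 / 3
  q[nuc & b$resname == "MG"] <- 2
  drop <- abs(q) > 0 & abs(q) < significance
  if (his_fractional) drop <- drop & !his
  q[drop] <- 0
  topology$beads$charge <- q
  topology
}

# ---------------------------------------------------------------------------
# P-site contact groups

# Shared constructor used by both the real pipeline and the toy fixtures.
make_psite_group <- function(site, chain, tyr, window, pairs, trigger,
                             role, cis) {
  list(site = site, chain = chain, tyr = tyr, window = window,
       pairs = pairs, trigger = trigger, role = role, cis = cis,
       tag = paste0("psite:", site, ":", role),
       enabled = TRUE, removed = FALSE)
}

#' Build P-site contact groups from docked-complex contact lists
#'
#' For each P-site definition, creates the productive trigger group (the
#' tyrosine/catalytic-site contacts of the receiver active site whose
#' simultaneous formation defines a binding event) and, mirrored onto the
#' activator active site, a non-terminating monitoring group with identical
#' \code{sigma} values; both copies of a P-site reuse one contact template.
#' The corresponding attractive terms are appended to the topology's native
#' contact set under the group's tag.
#'
#' @param topology a \code{cg_topology}.
#' @param definitions list of P-site definitions; each a list with
#'   \code{site} (id, e.g. "992A"), \code{chain}, \code{resno} (target
#'   tyrosine), and \code{contacts}: data.frame with \code{offset} (-4..4
#'   relative to the tyrosine, 0 = tyrosine), \code{partner_resno} (receiver
#'   active-site residue) and \code{sigma} (native pseudo-atom separation,
#'   A).
#' @param receiver_chain chain id of the catalytically engaged monomer.
#' @param activator_chain chain id of the allosteric activator monomer.
#' @param trigger_size declared number of tyrosine/active-site contacts
#'   (validated against the offset-0 contact count).
#' @param validate error when the tyrosine contact count differs from
#'   \code{trigger_size}.
#' @param eps well depth for the P-site attractive terms, kcal/mol.
#' @return Topology with \code{psite_groups} and psite-tagged contacts added.
#' @export
build_psite_groups <- function(topology, definitions, receiver_chain,
                               activator_chain, trigger_size = 9,
                               validate = TRUE, eps = 0.6) {
  b <- topology$beads
  bead_at <- function(chain, resno) {
    i <- which(b$chain == chain & b$resno == resno & b$kind == "residue")
    if (length(i) != 1) stop("no bead for ", chain, ":", resno)
    i
  }
  for (def in definitions) {
    ntyr <- sum(def$contacts$offset == 0)
    if (validate && ntyr != trigger_size)
      stop("P-site ", def$site, ": tyrosine contact count ", ntyr,
           " != declared trigger size ", trigger_size)
    window <- vapply(def$resno + (-4:4), function(r) bead_at(def$chain, r),
                     integer(1))
    for (role in c("productive", "mirror")) {
      target_chain <- if (role == "productive") receiver_chain
                      else activator_chain
      pairs <- data.frame(
        i = vapply(def$resno + def$contacts$offset,
                   function(r) bead_at(def$chain, r), integer(1)),
        j = vapply(def$contacts$partner_resno,
                   function(r) bead_at(target_chain, r), integer(1)),
        sigma = def$contacts$sigma,
        offset = def$contacts$offset)
      g <- make_psite_group(def$site, def$chain,
                            tyr = bead_at(def$chain, def$resno),
                            window = window,
                            pairs = pairs, trigger = ntyr, role = role,
                            cis = identical(def$chain, receiver_chain))
      topology$psite_groups <- c(topology$psite_groups, list(g))
      topology$contacts <- rbind(topology$contacts, data.frame(
        i = pmin(pairs$i, pairs$j), j = pmax(pairs$i, pairs$j),
        sigma = pairs$sigma, eps = eps, tag = g$tag, active = TRUE))
    }
  }
  topology
}

#' Read P-site definitions from JSON
#'
#' @param path JSON document: array of objects with fields \code{site},
#'   \code{chain}, \code{resno} and \code{contacts} (array of objects with
#'   \code{offset}, \code{partner_resno}, \code{sigma}).
#' @return List of definitions for \code{\link{build_psite_groups}}.
#' @export
read_psite_definitions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(k) {
    list(site = raw$site[k], chain = raw$chain[k], resno = raw$resno[k],
         contacts = as.data.frame(raw$contacts[[k]]))
  })
}
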