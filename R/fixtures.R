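# Deterministic synthetic toy systems: two folded pseudo-kinase domains in
# an asymmetric dimer, membrane-spanning helices, and disordered C-terminal
# tails carrying P-sites at chosen tether distances.  Fixtures exercise the
# production trigger machinery, force field and propagator unchanged.

#' Specification of a synthetic toy dimer
#'
#' @param fold_size beads per folded pseudo-kinase domain (serpentine path
#'   through a compact 3 x 3 x L grid, 3.8 A spacing).
#' @param tm_length beads per transmembrane helix (spans the 33 A slab).
#' @param ecd_length beads of the extracellular stub.
#' @param linker_length beads joining the membrane to the fold.
#' @param tethers named list (one entry per chain, \code{A} = receiver,
#'   \code{B} = activator) of tether distances: residues between the fold
#'   exit and each P-site tyrosine.
#' @param tail_extra tail residues beyond the last P-site window.
#' @param trigger_size tyrosine/catalytic-patch contacts per P-site group.
#' @param contact_cutoff pseudo-atom cutoff (A) defining fold and interface
#'   native contacts in the generated reference (toys have no all-atom
#'   reference, so contacts are defined at the bead level).
#' @param bond_length tail bond length, A.
#' @param charges \code{"psite-acidic"} decorates each P-site window with
#'   the acidic pattern (-1 at offsets -4, -2, -1) and puts +1 on the two
#'   patch beads closest to the docking point; \code{"none"} leaves the toy
#'   uncharged.
#' @param predock site id whose tyrosine is built docked in the receiver
#'   catalytic patch (all trigger contacts formed at start); \code{NULL} for
#'   a free tail.
#' @param seed integer; generation is bit-reproducible from it.
#' @return A \code{toy_dimer_spec}.
#' @export
toy_dimer_spec <- function(fold_size = 27, tm_length = 10, ecd_length = 4,
                           linker_length = 5,
                           tethers = list(A = c(10, 20, 60), B = c(10, 20, 60)),
                           tail_extra = 5, trigger_size = 9,
                           contact_cutoff = 8, bond_length = 3.8,
                           charges = c("psite-acidic", "none"),
                           predock = NULL, seed = 1) {
  charges <- match.arg(charges)
  stopifnot(fold_size >= 18, tm_length >= 2, all(unlist(tethers) >= 5))
  structure(list(fold_size = fold_size, tm_length = tm_length,
                 ecd_length = ecd_length, linker_length = linker_length,
                 tethers = tethers, tail_extra = tail_extra,
                 trigger_size = trigger_size,
                 contact_cutoff = contact_cutoff, bond_length = bond_length,
                 charges = charges, predock = predock, seed = seed),
            class = "toy_dimer_spec")
}

# serpentine path through a 3 x 3 x nz grid (consecutive beads adjacent)
grid_serpentine <- function(n, spacing) {
  nz <- ceiling(n / 9)
  pts <- NULL
  for (iz in seq_len(nz)) {
    ys <- if (iz %% 2) 1:3 else 3:1
    for (iy in ys) {
      xs <- if ((iz + iy) %% 2) 1:3 else 3:1
      for (ix in xs) pts <- rbind(pts, c(ix, iy, iz))
    }
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  sweep(pts, 2, c(2, 2, (nz + 1) / 2)) * spacing
}

unitv <- function(v) v / sqrt(sum(v^2))

# Constrained self-avoiding walk of nsteps bonds from `anchor` that lands
# exactly on `target`: candidates are biased toward the target just enough
# to stay reachable with the remaining bonds, keep clear of `occupied`, and
# (until the final approach) keep out of the funnel around the target.
# Returns an nsteps x 3 matrix of bead positions (last row == target), or
# NULL if no clash-free walk was found.
routed_walk <- function(anchor, target, nsteps, bl, occupied,
                        clash = 3.4, zmax = -18, tries = 150,
                        attempts = 40) {
  for (att in seq_len(attempts)) {
    path <- matrix(NA_real_, nsteps, 3)
    prev <- anchor
    prev_dir <- unitv(target - anchor + c(0, 0, -0.1))
    failed <- FALSE
    for (k in seq_len(nsteps)) {
      rem <- nsteps - k
      if (rem == 0) {
        if (sqrt(sum((target - prev)^2)) > 1.35 * bl ||
            sqrt(sum((target - prev)^2)) < 0.6 * bl) { failed <- TRUE; break }
        path[k, ] <- target
        break
      }
      ok <- FALSE
      for (tr in seq_len(tries)) {
        rnd <- unitv(c(stats::rnorm(1), stats::rnorm(1), stats::rnorm(1)))
        togo <- sqrt(sum((target - prev)^2))
        w <- 2.5 * (togo / ((rem + 1) * bl))^2
        dir <- unitv(0.6 * prev_dir + w * unitv(target - prev) + 0.9 * rnd)
        cand <- prev + dir * bl
        dt2 <- sqrt(sum((target - cand)^2))
        if (dt2 > 0.9 * rem * bl) next          # target must stay reachable
        if (rem > 2 && dt2 < 4) next            # stay out of the funnel
        if (cand[3] > zmax) next
        allpts <- rbind(occupied, path[seq_len(k - 1), , drop = FALSE])
        if (min_pair_dist(matrix(cand, 1), allpts) < clash) next
        path[k, ] <- cand
        prev <- cand
        prev_dir <- dir
        ok <- TRUE
        break
      }
      if (!ok) { failed <- TRUE; break }
    }
    if (!failed && !anyNA(path)) return(path)
  }
  NULL
}

#' Generate a synthetic toy dimer
#'
#' Builds the full coarse-grained system from a \code{toy_dimer_spec}: two
#' compact folded domains held together by interface native contacts, each
#' anchored to a membrane-spanning helix confined in the slab, with a
#' disordered tail carrying P-site tyrosines at the specified tether
#' distances.  Each monomer carries a catalytic patch (nine surface beads on
#' opposite faces of the two folds), a gamma-phosphate stand-in bead bonded
#' into the patch, and a designated catalytic-aspartate bead.  Every P-site
#' gets a productive trigger group against the receiver (chain A) patch and
#' a mirrored non-terminating group against the activator patch, with
#' identical contact templates.
#'
#' @param spec a \code{toy_dimer_spec}.
#' @return A \code{cg_topology} with contacts, psite groups and catalytic
#'   metadata; deterministic given the spec's seed.
#' @export
make_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  bl <- spec$bond_length
  coords <- NULL; beads <- NULL
  chain_info <- list()
  skel <- list()
  # pass 1: deterministic skeletons (membrane stub, TM helix, linker, fold,
  # catalytic patch, docking point, gamma-phosphate position)
  for (ch in c("A", "B")) {
    s <- if (ch == "A") -1 else 1
    xc <- s * 6.5
    patch_dir <- c(0, if (ch == "A") -1 else 1, 0)
    ecd <- cbind(xc, 0, 16.5 + bl * rev(seq_len(spec$ecd_length)))
    tmh <- cbind(xc, 0, seq(16.5, -16.5, length.out = spec$tm_length))
    lk <- cbind(xc, 0, seq(-16.5 - bl, -16.5 - bl * spec$linker_length,
                           by = -bl))
    fold_local <- grid_serpentine(spec$fold_size, bl)
    # orient the serpentine so the chain exits on the patch face: the tail
    # is tethered next to its own catalytic patch, as in the kinase-proximal
    # architecture the toys emulate
    if (ch == "A") fold_local[, 2] <- -fold_local[, 2]
    fold_center <- c(xc, 0, min(lk[, 3]) - bl - (max(fold_local[, 3]) -
                                                 min(fold_local[, 3])) / 2)
    fold <- sweep(fold_local, 2, fold_center, "+")
    target <- fold_center + patch_dir * 10
    dfold <- sqrt(rowSums(sweep(fold, 2, target)^2))
    patch_local <- order(dfold)[seq_len(spec$trigger_size)]
    patch_xyz <- fold[patch_local, , drop = FALSE]
    normal <- unitv(patch_dir)
    dock <- colMeans(patch_xyz) + normal * 5.5
    patch_local <- patch_local[order(sqrt(rowSums(
      sweep(patch_xyz, 2, dock)^2)))]
    patch_xyz <- fold[patch_local, , drop = FALSE]
    sigma <- sqrt(rowSums(sweep(patch_xyz, 2, dock)^2))
    gamma_xyz <- colMeans(patch_xyz) + normal * 1.5
    skel[[ch]] <- list(ecd = ecd, tm = tmh, lk = lk, fold = fold,
                       patch_local = patch_local, sigma = sigma,
                       dock = dock, gamma_xyz = gamma_xyz,
                       asp_local = patch_local[1], s = s,
                       patch_dir = patch_dir)
  }
  # keep free tails away from both docking funnels
  avoid_pts <- rbind(matrix(skel$A$dock, 1), matrix(skel$B$dock, 1),
                     matrix(skel$A$gamma_xyz, 1), matrix(skel$B$gamma_xyz, 1))
  avoid_radius <- 7
  # pass 2: stochastic tails, clash-checked against everything already built
  with_seed_(spec$seed, {
    for (ch in c("A", "B")) {
      sk <- skel[[ch]]
      xyz <- rbind(sk$ecd, sk$tm, sk$lk, sk$fold)
      region <- c(rep("extracellular", nrow(sk$ecd)),
                  rep("transmembrane", nrow(sk$tm)),
                  rep("modeled", nrow(sk$lk)),
                  rep("structured", nrow(sk$fold)))
      resname <- c(rep("S", nrow(sk$ecd)), rep("L", nrow(sk$tm)),
                   rep("G", nrow(sk$lk)), rep("A", nrow(sk$fold)))
      fold_range <- (nrow(xyz) - spec$fold_size + 1):nrow(xyz)

      tail_len <- max(spec$tethers[[ch]]) + 4 + spec$tail_extra
      anchor <- sk$fold[nrow(sk$fold), ]
      tail <- matrix(NA_real_, tail_len, 3)
      predock_here <- !is.null(spec$predock) &&
        grepl(paste0(ch, "$"), spec$predock)
      predock_tether <- if (predock_here)
        spec$tethers[[ch]][which(paste0("t", spec$tethers[[ch]], ch) ==
                                 spec$predock)[1]] else NA
      other <- setdiff(c("A", "B"), ch)
      occupied <- rbind(coords, xyz, matrix(sk$gamma_xyz, 1),
                        skel[[other]]$ecd, skel[[other]]$tm,
                        skel[[other]]$lk, skel[[other]]$fold,
                        matrix(skel[[other]]$gamma_xyz, 1))
      if (predock_here && !is.na(predock_tether)) {
        # docked start: tail routed through the receiver docking point
        if (ch != "A")
          stop("predocked starts are built against the receiver (chain A)")
        dock <- skel$A$dock
        L <- predock_tether * bl
        d0 <- sqrt(sum((dock - anchor)^2))
        if (L < d0)
          stop("tail too short to reach the catalytic patch: tether ",
               predock_tether, " (needs >= ", ceiling(d0 / bl), ")")
        path <- routed_walk(anchor, dock, predock_tether, bl, occupied)
        if (is.null(path))
          stop("cannot route the docked tail into the catalytic patch")
        tail[seq_len(predock_tether), ] <- path
        start_at <- predock_tether + 1
        prev_dir <- unitv(c(0, sk$patch_dir[2], -1))
      } else {
        # the shortest-tether P-site of each chain emulates the
        # kinase-proximal architecture: its initial path skirts the mouth
        # of its own monomer's docking funnel (well outside the contact
        # minima), so sequence proximity translates into spatial proximity
        t_min <- min(spec$tethers[[ch]])
        waypoint <- sk$dock + unitv(sk$patch_dir) * 5.5
        L <- t_min * bl
        d0 <- sqrt(sum((waypoint - anchor)^2))
        if (L < d0)
          stop("tail too short to reach the catalytic patch: tether ",
               t_min, " (needs >= ", ceiling(d0 / bl), ")")
        path <- routed_walk(anchor, waypoint, t_min, bl, occupied)
        if (is.null(path))
          stop("cannot route the kinase-proximal tail clear of the fold")
        tail[seq_len(t_min), ] <- path
        start_at <- t_min + 1
        prev_dir <- unitv(c(0, sk$patch_dir[2] * 0.5, -1))
      }
      if (start_at <= tail_len) {
        dir0 <- prev_dir
        built <- FALSE
        for (attempt in 1:25) {   # restart the walk if it gets boxed in
          prev_dir <- dir0
          tail[start_at:tail_len, ] <- NA_real_
          failed <- FALSE
          for (k in start_at:tail_len) {
            prev <- if (k == 1) anchor else tail[k - 1, ]
            ok <- FALSE
            for (try in 1:120) {
              rnd <- unitv(c(stats::rnorm(1), stats::rnorm(1),
                             stats::rnorm(1)))
              dir <- unitv(prev_dir + 0.9 * rnd)
              cand <- prev + dir * bl
              if (cand[3] > -18) next
              # tyrosine beads carry the trigger wells: keep them out of
              # the docking funnels so no contact starts inside its minimum
              if (k %in% spec$tethers[[ch]] &&
                  min_pair_dist(matrix(cand, 1), avoid_pts) < avoid_radius)
                next
              allpts <- rbind(occupied, tail[seq_len(k - 1), , drop = FALSE])
              if (min_pair_dist(matrix(cand, 1), allpts) < 3.6) next
              tail[k, ] <- cand
              prev_dir <- dir
              ok <- TRUE
              break
            }
            if (!ok) { failed <- TRUE; break }
          }
          if (!failed) { built <- TRUE; break }
        }
        if (!built)
          stop("toy tail generation failed (chain ", ch,
               "); loosen the geometry")
      }
      xyz <- rbind(xyz, tail)
      region <- c(region, rep("modeled", tail_len))
      resname <- c(resname, rep("G", tail_len))
      n_res <- nrow(xyz)

      chain_info[[ch]] <- list(
        offset = if (is.null(beads)) 0L else nrow(beads),
        n_res = n_res, fold_range = fold_range,
        patch_local = sk$patch_local, sigma = sk$sigma, dock = sk$dock,
        gamma_xyz = sk$gamma_xyz, asp_local = sk$asp_local,
        tail_start = n_res - tail_len + 1)

      beads <- rbind(beads, data.frame(
        chain = ch, resno = seq_len(n_res), resname = resname,
        kind = "residue", region = region, complex_id = NA_integer_,
        charge = 0, radius = RESIDUE_RADIUS,
        is_tm = region == "transmembrane",
        side = ifelse(region == "extracellular", 1L,
                      ifelse(region == "transmembrane", 0L, -1L)),
        z0 = ifelse(region == "transmembrane", xyz[, 3], NA_real_),
        stringsAsFactors = FALSE))
      coords <- rbind(coords, xyz)
    }
  })

  # gamma-phosphate stand-in beads (nucleotide kind), appended after chains
  for (ch in c("A", "B")) {
    ci <- chain_info[[ch]]
    beads <- rbind(beads, data.frame(
      chain = ch, resno = ci$n_res + 1L, resname = "P3", kind = "nucleotide",
      region = "nucleotide-complex",
      complex_id = if (ch == "A") 1L else 2L, charge = 0,
      radius = NUCLEOTIDE_RADIUS, is_tm = FALSE, side = -1L, z0 = NA_real_,
      stringsAsFactors = FALSE))
    coords <- rbind(coords, matrix(ci$gamma_xyz, 1))
    chain_info[[ch]]$gamma_bead <- nrow(beads)
  }
  rownames(beads) <- NULL

  # bonded terms along each chain + gamma anchoring bonds
  bonds <- empty_bonds(); angles <- empty_angles(); dihs <- empty_dihedrals()
  for (ch in c("A", "B")) {
    ci <- chain_info[[ch]]
    idx <- ci$offset + seq_len(ci$n_res)
    for (q in seq_len(length(idx) - 1)) {
      i <- idx[q]; j <- idx[q + 1]
      bonds <- rbind(bonds, data.frame(
        i = i, j = j, r_eq = sqrt(sum((coords[i, ] - coords[j, ])^2))))
    }
    for (q in seq_len(length(idx) - 2)) {
      tri <- idx[q:(q + 2)]
      angles <- rbind(angles, data.frame(
        i = tri[1], j = tri[2], k = tri[3],
        theta_eq = angle_of(coords[tri[1], ], coords[tri[2], ],
                            coords[tri[3], ])))
    }
    for (q in seq_len(length(idx) - 3)) {
      qu <- idx[q:(q + 3)]
      if (!dihedral_defined(coords[qu[1], ], coords[qu[2], ],
                            coords[qu[3], ], coords[qu[4], ])) next
      dihs <- rbind(dihs, data.frame(
        i = qu[1], j = qu[2], k = qu[3], l = qu[4],
        phi_native = dihedral_of(coords[qu[1], ], coords[qu[2], ],
                                 coords[qu[3], ], coords[qu[4], ])))
    }
    # anchor the gamma bead to its three nearest patch beads
    gb <- ci$gamma_bead
    pidx <- ci$offset + ci$fold_range[1] - 1L + ci$patch_local
    near <- pidx[order(sqrt(rowSums(sweep(coords[pidx, , drop = FALSE], 2,
                                          coords[gb, ])^2)))[1:3]]
    for (j in near)
      bonds <- rbind(bonds, data.frame(
        i = min(gb, j), j = max(gb, j),
        r_eq = sqrt(sum((coords[gb, ] - coords[j, ])^2))))
    chain_info[[ch]]$gamma_bonded <- near
  }

  # native contacts: fold (intra-chain) + interface (inter-chain), defined
  # at the pseudo-atom level for generated toys
  contacts <- empty_contacts()
  fold_beads <- unlist(lapply(c("A", "B"), function(ch) {
    ci <- chain_info[[ch]]
    ci$offset + ci$fold_range[1] - 1L + seq_len(length(ci$fold_range))
  }))
  nf <- length(fold_beads)
  for (a in seq_len(nf - 1)) for (bq in (a + 1):nf) {
    i <- fold_beads[a]; j <- fold_beads[bq]
    same <- beads$chain[i] == beads$chain[j]
    if (same && abs(beads$resno[i] - beads$resno[j]) < 3) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r <= spec$contact_cutoff)
      contacts <- rbind(contacts, data.frame(
        i = i, j = j, sigma = r, eps = 0.6,
        tag = if (same) "fold" else "interface", active = TRUE))
  }
  # gamma-phosphate beads sit inside their patch: native contacts to all
  # nearby fold beads (nucleotide-site treatment), bonds excepted
  for (ch in c("A", "B")) {
    ci <- chain_info[[ch]]
    gb <- ci$gamma_bead
    for (j in fold_beads) {
      if (j %in% ci$gamma_bonded) next
      r <- sqrt(sum((coords[gb, ] - coords[j, ])^2))
      if (r <= spec$contact_cutoff)
        contacts <- rbind(contacts, data.frame(
          i = min(gb, j), j = max(gb, j), sigma = r, eps = 0.6,
          tag = "nucleotide-site", active = TRUE))
    }
  }

  top <- cg_topology(coords, beads, bonds, angles, dihs, contacts)

  # P-site groups: productive against the receiver (A) patch, mirrored
  # against the activator (B) patch with the same sigma template.
  patch_beads <- lapply(c("A", "B"), function(ch) {
    ci <- chain_info[[ch]]
    ci$offset + ci$fold_range[1] - 1L + ci$patch_local
  })
  names(patch_beads) <- c("A", "B")
  sigma_template <- chain_info$A$sigma
  for (ch in c("A", "B")) {
    ci <- chain_info[[ch]]
    for (tt in spec$tethers[[ch]]) {
      site <- paste0("t", tt, ch)
      tyr <- ci$offset + ci$tail_start - 1L + tt
      top$beads$resname[tyr] <- "Y"
      window <- (tyr - 4):(tyr + 4)
      for (role in c("productive", "mirror")) {
        tgt <- if (role == "productive") "A" else "B"
        pairs <- data.frame(i = tyr, j = patch_beads[[tgt]],
                            sigma = sigma_template, offset = 0)
        g <- make_psite_group(site, ch, tyr, window, pairs,
                              trigger = spec$trigger_size, role = role,
                              cis = ch == "A")
        top$psite_groups <- c(top$psite_groups, list(g))
        con_new <- data.frame(
          i = pmin(pairs$i, pairs$j), j = pmax(pairs$i, pairs$j),
          sigma = pairs$sigma, eps = 0.6, tag = g$tag, active = TRUE)
        # gamma-phosphate attraction: attractive, not a trigger member
        gb <- chain_info[[tgt]]$gamma_bead
        con_new <- rbind(con_new, data.frame(
          i = min(tyr, gb), j = max(tyr, gb), sigma = 4.0, eps = 0.6,
          tag = g$tag, active = TRUE))
        top$contacts <- rbind(top$contacts, con_new)
      }
    }
  }

  # charge decoration
  if (spec$charges == "psite-acidic") {
    for (g in top$psite_groups) {
      if (g$role != "productive") next
      top$beads$charge[g$tyr - 4] <- -1
      top$beads$charge[g$tyr - 2] <- -1
      top$beads$charge[g$tyr - 1] <- -1
      top$beads$resname[c(g$tyr - 4, g$tyr - 2, g$tyr - 1)] <- "D"
    }
    for (ch in c("A", "B"))
      top$beads$charge[patch_beads[[ch]][1:2]] <- 1
  }

  top$catalytic <- list(
    receiver = "A",
    A = list(patch = patch_beads$A, gamma = chain_info$A$gamma_bead,
             asp = chain_info$A$offset + chain_info$A$fold_range[1] - 1L +
               chain_info$A$asp_local, dock = chain_info$A$dock),
    B = list(patch = patch_beads$B, gamma = chain_info$B$gamma_bead,
             asp = chain_info$B$offset + chain_info$B$fold_range[1] - 1L +
               chain_info$B$asp_local, dock = chain_info$B$dock))
  top$spec <- spec
  top
}

#' Vary one P-site tether distance
#'
#' Returns a list of specs identical to \code{base} except for the tether
#' distance of one P-site; used to probe sequence-proximity (cis-bias)
#' effects.
#'
#' @param base a \code{toy_dimer_spec}.
#' @param lengths tether distances to substitute.
#' @param chain,site_index which P-site to vary.
#' @return List of \code{toy_dimer_spec}, one per length.
#' @export
make_tether_series <- function(base, lengths, chain = "A", site_index = 1) {
  lapply(lengths, function(L) {
    sp <- base
    sp$tethers[[chain]][site_index] <- L
    sp
  })
}

#' Deterministic hash of a topology
#' @param topology a \code{cg_topology}.
#' @return md5 string of the serialized object.
#' @export
topology_hash <- function(topology) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(topology, f, version = 2)
  unname(tools::md5sum(f))
}

#' Micro-fixtures with analytic reference behaviour
#'
#' A library of minimal systems used throughout the test suite: an isolated
#' bond, angle and dihedral, a charged pair, a free bead, wall- and
#' TM-restraint test beads, and toy-dimer starts with the P-site pre-docked
#' (all trigger contacts formed) or near-docked (one trigger contact
#' rendered geometrically unattainable, so the trigger can never complete).
#'
#' @return Named list; each element has \code{topology} and a \code{ref}
#'   list with the analytic reference quantities.
#' @export
make_unit_systems <- function() {
  mk_beads <- function(n, chain = "A", charge = 0, side = 0L, is_tm = FALSE,
                       z0 = NA_real_) {
    data.frame(chain = chain, resno = seq_len(n), resname = "G",
               kind = "residue", region = "modeled",
               complex_id = NA_integer_, charge = charge,
               radius = RESIDUE_RADIUS, is_tm = is_tm, side = side, z0 = z0,
               stringsAsFactors = FALSE)
  }
  out <- list()
  out$bond2 <- list(
    topology = cg_topology(rbind(c(0, 0, 0), c(3.8, 0, 0)), mk_beads(2),
                           bonds = data.frame(i = 1, j = 2, r_eq = 3.8)),
    ref = list(r_eq = 3.8))
  out$angle3 <- list(
    topology = cg_topology(rbind(c(3.8, 0, 0), c(0, 0, 0), c(0, 3.8, 0)),
                           mk_beads(3),
                           bonds = data.frame(i = 1:2, j = 2:3,
                                              r_eq = c(3.8, 3.8)),
                           angles = data.frame(i = 1, j = 2, k = 3,
                                               theta_eq = pi / 2)),
    ref = list(theta_eq = pi / 2))
  dih_xyz <- rbind(c(0, 1.5, -1), c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0.9))
  out$dihedral4 <- list(
    topology = cg_topology(
      dih_xyz, mk_beads(4),
      bonds = data.frame(i = 1:3, j = 2:4,
                         r_eq = c(sqrt(sum((dih_xyz[1, ] - dih_xyz[2, ])^2)),
                                  1.5,
                                  sqrt(sum((dih_xyz[3, ] - dih_xyz[4, ])^2)))),
      dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                             phi_native = dihedral_of(dih_xyz[1, ],
                                                      dih_xyz[2, ],
                                                      dih_xyz[3, ],
                                                      dih_xyz[4, ]))),
    ref = list(phi_native = dihedral_of(dih_xyz[1, ], dih_xyz[2, ],
                                        dih_xyz[3, ], dih_xyz[4, ])))
  bb <- rbind(mk_beads(1, "A", charge = 1), mk_beads(1, "B", charge = 1))
  out$charged_pair <- list(
    topology = cg_topology(rbind(c(0, 0, 0), c(10, 0, 0)), bb),
    ref = list(r = 10, q1 = 1, q2 = 1))
  out$free_bead <- list(
    topology = cg_topology(matrix(0, 1, 3), mk_beads(1)),
    ref = list(radius = RESIDUE_RADIUS))
  out$wall_bead <- list(
    topology = cg_topology(matrix(c(0, 0, 20), 1), mk_beads(1, side = 1L)),
    ref = list(z_wall = 16.5))
  out$tm_bead <- list(
    topology = cg_topology(matrix(0, 1, 3),
                           mk_beads(1, is_tm = TRUE, z0 = 0)),
    ref = list(z0 = 0))
  predock_spec <- toy_dimer_spec(tethers = list(A = 10, B = 10),
                                 predock = "t10A", seed = 11)
  pre <- make_toy_dimer(predock_spec)
  out$pre_docked <- list(topology = pre,
                         ref = list(site = "t10A",
                                    trigger = predock_spec$trigger_size))
  near <- pre
  for (k in seq_along(near$psite_groups)) {
    g <- near$psite_groups[[k]]
    if (g$site == "t10A" && g$role == "productive") {
      old_sigma <- g$pairs$sigma[1]
      g$pairs$sigma[1] <- 0.8  # unreachable: repulsive core blocks r <= 0.96
      near$psite_groups[[k]] <- g
      sel <- near$contacts$tag == g$tag &
        (pmin(near$contacts$i, near$contacts$j) ==
           min(g$pairs$i[1], g$pairs$j[1])) &
        (pmax(near$contacts$i, near$contacts$j) ==
           max(g$pairs$i[1], g$pairs$j[1]))
      near$contacts$sigma[which(sel)[1]] <- 0.8
    }
  }
  out$near_docked <- list(topology = near,
                          ref = list(site = "t10A",
                                     formed = predock_spec$trigger_size - 1))
  out
}
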