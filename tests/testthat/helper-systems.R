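# Shared fixtures and oracles used across the suite.

ff0 <- go_forcefield()

# Toy systems integrate at half the production step: the generated lattice
# folds are stiffer than crystallographic C-alpha folds (see the methods
# vignette), and the first-order integrator needs the extra margin.
cfg_toy <- function(...) bd_config(timestep_fs = 62.5, ...)

mk_beads <- function(n, chain = "A", charge = 0, side = 0L, is_tm = FALSE,
                     z0 = NA_real_, region = "modeled", resname = "G",
                     radius = 5.3) {
  data.frame(chain = chain, resno = seq_len(n), resname = resname,
             kind = "residue", region = region, complex_id = NA_integer_,
             charge = charge, radius = radius, is_tm = is_tm, side = side,
             z0 = z0, stringsAsFactors = FALSE)
}

# chain topology with all bonded terms taken from the given coordinates
mk_chain_top <- function(xyz, beads = mk_beads(nrow(xyz)),
                         contacts = NULL) {
  n <- nrow(xyz)
  bonds <- if (n > 1)
    data.frame(i = 1:(n - 1), j = 2:n,
               r_eq = sqrt(rowSums((xyz[-1, , drop = FALSE] -
                                    xyz[-n, , drop = FALSE])^2)))
  else gophos:::empty_bonds()
  angles <- if (n > 2)
    data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
               theta_eq = sapply(1:(n - 2), function(q)
                 gophos:::angle_of(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ])))
  else gophos:::empty_angles()
  dih <- if (n > 3)
    data.frame(i = 1:(n - 3), j = 2:(n - 2), k = 3:(n - 1), l = 4:n,
               phi_native = sapply(1:(n - 3), function(q)
                 gophos:::dihedral_of(xyz[q, ], xyz[q + 1, ], xyz[q + 2, ],
                                      xyz[q + 3, ])))
  else gophos:::empty_dihedrals()
  if (is.null(contacts)) contacts <- gophos:::empty_contacts()
  cg_topology(xyz, beads, bonds, angles, dih, contacts)
}

# random bent chain (reproducible)
random_chain_xyz <- function(n, seed, step = 3.8) {
  gophos:::with_seed_(seed, {
    xyz <- matrix(0, n, 3)
    d <- c(1, 0, 0)
    for (k in 2:n) {
      d <- d + 0.6 * rnorm(3)
      d <- d / sqrt(sum(d^2))
      xyz[k, ] <- xyz[k - 1, ] + step * d
    }
    xyz
  })
}

# central finite-difference forces (independent oracle for the gradients)
fd_forces <- function(fun, top, ff, coords, h = 1e-5) {
  num <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (c in 1:3) {
    cp <- coords; cm <- coords
    cp[i, c] <- cp[i, c] + h
    cm[i, c] <- cm[i, c] - h
    num[i, c] <- -(fun(top, ff, cp)$energy - fun(top, ff, cm)$energy) / (2 * h)
  }
  num
}

kabsch_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  s <- svd(t(a) %*% b)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sqrt(mean(rowSums((b %*% R - a)^2)))
}

# small all-atom helix (backbone only) as an annotated structure
helix_structure <- function(n_res, chain = "A", label = "structured") {
  lib <- dipeptide_library()
  frag <- lib$fragments$helix
  atoms <- NULL
  # grow by repeated dipeptide alignment, all in code
  cur <- frag[frag$res == 1, ]
  cur$resno <- 1L
  atoms <- cur
  for (k in 2:n_res) {
    last <- atoms[atoms$resno == k - 1 & atoms$name %in% c("N", "CA", "C"), ]
    last <- last[match(c("N", "CA", "C"), last$name), ]
    a1 <- frag[frag$res == 1 & frag$name %in% c("N", "CA", "C"), ]
    a1 <- a1[match(c("N", "CA", "C"), a1$name), ]
    mapf <- gophos:::kabsch_map(as.matrix(a1[, c("x", "y", "z")]),
                                as.matrix(last[, c("x", "y", "z")]))
    new <- frag[frag$res == 2, ]
    xyz <- mapf(as.matrix(new[, c("x", "y", "z")]))
    new$x <- xyz[, 1]; new$y <- xyz[, 2]; new$z <- xyz[, 3]
    new$resno <- k
    atoms <- rbind(atoms, new)
  }
  adf <- data.frame(eleno = seq_len(nrow(atoms)), elety = atoms$name,
                    resid = "ALA", chain = chain, resno = atoms$resno,
                    x = atoms$x, y = atoms$y, z = atoms$z,
                    stringsAsFactors = FALSE)
  annotate_structure(adf, data.frame(chain = chain, first = 1, last = n_res,
                                     label = label))
}

# brute-force all-atom native-contact oracle
contacts_oracle <- function(structure, topology, cutoff = 5.5) {
  b <- topology$beads
  at <- structure$atoms
  res <- which(b$kind == "residue")
  out <- NULL
  for (a in seq_along(res)) for (q in seq_along(res)) {
    if (q <= a) next
    i <- res[a]; j <- res[q]
    if (b$chain[i] == b$chain[j] && abs(b$resno[i] - b$resno[j]) < 3) next
    ga <- as.matrix(at[at$chain == b$chain[i] & at$resno == b$resno[i],
                       c("x", "y", "z")])
    gb <- as.matrix(at[at$chain == b$chain[j] & at$resno == b$resno[j],
                       c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(ga^2), rowSums(gb^2), "+") -
                     2 * ga %*% t(gb)))
    if (dmin <= cutoff) out <- rbind(out, c(i, j))
  }
  out
}
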