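# All-atom structure I/O with per-residue region annotation, and the
# dipeptide-library build-up algorithm for modeling missing terminal
# segments.

REGION_LABELS <- c("structured", "modeled", "transmembrane", "extracellular",
                   "intracellular", "ligand", "nucleotide-complex")

#' Read an annotated all-atom structure
#'
#' Parses a PDB file (via bio3d) and attaches a region label to every
#' residue.  Each residue must be covered by exactly one range of the region
#' map; unmapped residues and overlapping ranges are errors, and structures
#' with insertion codes are rejected (renumber before use).
#'
#' @param path PDB file.
#' @param region_map data.frame with columns \code{chain}, \code{first},
#'   \code{last}, \code{label}; labels must be one of structured, modeled,
#'   transmembrane, extracellular, intracellular, ligand,
#'   nucleotide-complex.
#' @return An \code{annotated_structure}: \code{atoms} (eleno, elety, resid,
#'   chain, resno, x, y, z), \code{regions} (chain, resno, region) and a
#'   \code{provenance} note.
#' @export
read_structure <- function(path, region_map) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0)
    stop("malformed PDB '", path, "': no ATOM/HETATM records")
  ins <- at$insert
  if (any(!is.na(ins) & ins != "" & ins != " "))
    stop("insertion codes are not supported; renumber the structure")
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      chain = ifelse(is.na(at$chain) | at$chain == "", "A",
                                     at$chain),
                      resno = at$resno, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in '", path, "'")
  annotate_structure(atoms, region_map,
                     provenance = paste("read from", basename(path)))
}

#' Annotate an atom table with region labels
#'
#' @param atoms atom data.frame (eleno, elety, resid, chain, resno, x, y, z).
#' @param region_map see \code{\link{read_structure}}.
#' @param provenance free-text provenance note.
#' @return An \code{annotated_structure}.
#' @export
annotate_structure <- function(atoms, region_map, provenance = "") {
  if (!all(region_map$label %in% REGION_LABELS))
    stop("unknown region label(s): ",
         paste(setdiff(region_map$label, REGION_LABELS), collapse = ", "))
  res <- unique(atoms[, c("chain", "resno")])
  res <- res[order(res$chain, res$resno), ]
  lab <- rep(NA_character_, nrow(res))
  for (r in seq_len(nrow(region_map))) {
    hit <- res$chain == region_map$chain[r] &
      res$resno >= region_map$first[r] & res$resno <= region_map$last[r]
    if (any(!is.na(lab[hit])))
      stop("region map ranges overlap for chain ", region_map$chain[r])
    lab[hit] <- region_map$label[r]
  }
  if (any(is.na(lab)))
    stop("residues not covered by the region map: ",
         paste(paste0(res$chain[is.na(lab)], ":", res$resno[is.na(lab)]),
               collapse = ", "))
  regions <- data.frame(chain = res$chain, resno = res$resno, region = lab,
                        stringsAsFactors = FALSE)
  # transmembrane runs must be contiguous in sequence per chain
  for (ch in unique(regions$chain)) {
    tm <- regions$resno[regions$chain == ch & regions$region == "transmembrane"]
    if (length(tm) > 1 && any(diff(sort(tm)) != 1))
      stop("transmembrane residues of chain ", ch, " are not contiguous")
  }
  structure(list(atoms = atoms, regions = regions, provenance = provenance),
            class = "annotated_structure")
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat(sprintf("annotated_structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(x$regions), length(unique(x$atoms$chain))))
  print(table(x$regions$region))
  invisible(x)
}

#' Write an annotated structure to PDB
#'
#' @param structure an \code{annotated_structure}.
#' @param path output file.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ideal-geometry backbone construction (NeRF internal-to-cartesian placement)

nerf_place <- function(a, b, c, len, theta, phi) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-len * cos(theta), len * sin(theta) * cos(phi),
          len * sin(theta) * sin(phi))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

pracma_cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

# Backbone of a dipeptide (atoms N, CA, C, O per residue) with the given
# (phi2, psi1, psi2) torsions and ideal bond geometry.
build_dipeptide <- function(phi2, psi1, psi2) {
  deg <- pi / 180
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2 * deg; aCACN <- 116.2 * deg; aCNCA <- 121.7 * deg
  aCACO <- 120.8 * deg
  N1 <- c(0, 0, 0)
  CA1 <- c(bNCA, 0, 0)
  C1 <- CA1 + c(-bCAC * cos(aNCAC), bCAC * sin(aNCAC), 0)
  O1 <- nerf_place(N1, CA1, C1, bCO, aCACO, (psi1 + 180) * deg)
  N2 <- nerf_place(N1, CA1, C1, bCN, aCACN, psi1 * deg)
  CA2 <- nerf_place(CA1, C1, N2, bNCA, aCNCA, 180 * deg)   # trans omega
  C2 <- nerf_place(C1, N2, CA2, bCAC, aNCAC, phi2 * deg)
  O2 <- nerf_place(N2, CA2, C2, bCO, aCACO, (psi2 + 180) * deg)
  xyz <- rbind(N1, CA1, C1, O1, N2, CA2, C2, O2)
  colnames(xyz) <- c("x", "y", "z")
  data.frame(res = rep(1:2, each = 4),
             name = rep(c("N", "CA", "C", "O"), 2), xyz, row.names = NULL)
}

#' Dipeptide backbone fragment library
#'
#' A small packaged library of ideal dipeptide backbone conformers (alpha
#' helix, extended beta, polyproline II) used by the terminal build-up
#' algorithm.  The fragments are residue-type agnostic (backbone atoms only),
#' so every residue-type pair falls back to the same pool; users may supply
#' their own, larger library with the same layout.
#'
#' @return A \code{dipeptide_library}: list of fragments, each a data.frame
#'   with columns \code{res} (1 or 2), \code{name} (N/CA/C/O), \code{x},
#'   \code{y}, \code{z}.
#' @export
dipeptide_library <- function() {
  frags <- list(
    helix = build_dipeptide(phi2 = -57, psi1 = -47, psi2 = -47),
    extended = build_dipeptide(phi2 = -139, psi1 = 135, psi2 = 135),
    ppii = build_dipeptide(phi2 = -78, psi1 = 149, psi2 = 149))
  structure(list(fragments = frags), class = "dipeptide_library")
}

# Kabsch superposition of 3-point sets (rows): returns function mapping
# coordinates from the fragment frame into the target frame.
kabsch_map <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  function(x) sweep(sweep(x, 2, cf) %*% t(R), 2, ct, "+")
}

#' Extend a chain terminus with the dipeptide build-up algorithm
#'
#' Grows a chain one residue at a time: a dipeptide fragment is drawn at
#' random from the library, its first residue's backbone is superposed onto
#' the current terminal residue, and its second residue becomes the new
#' terminus, provided no atom of the newly placed residue comes closer than
#' \code{clash_radius} to any pre-existing atom (the bonded terminal residue
#' excepted).  Placement is retried with fresh fragments up to
#' \code{max_retries} times per step.  Pre-existing atoms are never moved.
#' New residues are labeled \code{modeled}.
#'
#' @param structure an \code{annotated_structure}.
#' @param chain chain id to extend.
#' @param direction \code{"C"} or \code{"N"}.
#' @param sequence character vector of residue names to append (may be
#'   empty, in which case the structure is returned unchanged).
#' @param library a \code{dipeptide_library}.
#' @param clash_radius minimum allowed distance between a newly placed atom
#'   and any pre-existing atom, A.
#' @param max_retries placement attempts per residue before failing.
#' @param seed RNG seed; runs are reproducible from it.
#' @return The extended \code{annotated_structure}.
#' @export
extend_terminus <- function(structure, chain, direction = c("C", "N"),
                            sequence, library = dipeptide_library(),
                            clash_radius = 2.5, max_retries = 50, seed = 1) {
  direction <- match.arg(direction)
  if (length(sequence) == 0) return(structure)
  atoms <- structure$atoms
  regions <- structure$regions
  sel <- atoms$chain == chain
  if (!any(sel)) stop("no such chain: ", chain)
  frags <- library$fragments
  with_seed_(seed, {
    for (k in seq_along(sequence)) {
      cres <- atoms$resno[sel]
      term_res <- if (direction == "C") max(cres) else min(cres)
      tsel <- sel & atoms$resno == term_res
      bb <- atoms[tsel & atoms$elety %in% c("N", "CA", "C"), ]
      bb <- bb[match(c("N", "CA", "C"), bb$elety), ]
      if (any(is.na(bb$eleno)))
        stop("terminal residue ", term_res, " of chain ", chain,
             " lacks a complete backbone")
      target <- as.matrix(bb[, c("x", "y", "z")])
      other <- as.matrix(atoms[!tsel, c("x", "y", "z")])
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        fr <- frags[[sample.int(length(frags), 1)]]
        anchor_res <- if (direction == "C") 1L else 2L
        new_res <- if (direction == "C") 2L else 1L
        anchor <- fr[fr$res == anchor_res & fr$name %in% c("N", "CA", "C"), ]
        anchor <- anchor[match(c("N", "CA", "C"), anchor$name), ]
        mapf <- kabsch_map(as.matrix(anchor[, c("x", "y", "z")]), target)
        newat <- fr[fr$res == new_res, ]
        newxyz <- mapf(as.matrix(newat[, c("x", "y", "z")]))
        if (nrow(other) == 0 ||
            min_pair_dist(newxyz, other) >= clash_radius) {
          new_resno <- term_res + if (direction == "C") 1L else -1L
          add <- data.frame(eleno = max(atoms$eleno) + seq_len(nrow(newat)),
                            elety = newat$name, resid = sequence[k],
                            chain = chain, resno = new_resno,
                            x = newxyz[, 1], y = newxyz[, 2], z = newxyz[, 3],
                            stringsAsFactors = FALSE)
          atoms <- rbind(atoms, add)
          regions <- rbind(regions,
                           data.frame(chain = chain, resno = new_resno,
                                      region = "modeled",
                                      stringsAsFactors = FALSE))
          sel <- atoms$chain == chain
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("terminal extension failed at step ", k, " of ",
             length(sequence), ": no clash-free placement in ",
             max_retries, " attempts")
    }
  })
  structure(list(atoms = atoms, regions = regions,
                 provenance = paste0(structure$provenance, "; extended ",
                                     chain, "/", direction, " by ",
                                     length(sequence), " residues")),
            class = "annotated_structure")
}

min_pair_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# ---------------------------------------------------------------------------
# Event tables and trajectory container

EVENT_COLUMNS <- c("trial", "seed", "site", "chain", "cis", "time_ns",
                   "structure_id")

#' Write a binding-event table as TSV
#'
#' One row per trial outcome with the fixed column order trial, seed, site,
#' chain, cis, time_ns, structure_id.  An empty table yields a header-only
#' file.
#'
#' @param records event-record data.frame (see
#'   \code{\link{run_binding_campaign}}).
#' @param path output file.
#' @export
write_event_table <- function(records, path) {
  df <- records[, EVENT_COLUMNS, drop = FALSE]
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write event table to '", path, "'")
  invisible(path)
}

#' Read a binding-event TSV
#' @param path file written by \code{\link{write_event_table}}.
#' @return data.frame of event records.
#' @export
read_event_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(EVENT_COLUMNS %in% names(df)))
    stop("not an event table: missing columns ",
         paste(setdiff(EVENT_COLUMNS, names(df)), collapse = ", "))
  df
}

#' Write a trajectory to a binary container
#'
#' Self-describing little-endian container: text header declaring units
#' (Angstrom / ns), frame count and bead count, then time stamps and
#' per-frame coordinates.
#'
#' @param frames list of N x 3 coordinate matrices.
#' @param times_ns frame time stamps, ns; must be strictly increasing.
#' @param path output file.
#' @export
write_trajectory <- function(frames, times_ns, path) {
  stopifnot(length(frames) == length(times_ns))
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  n <- if (length(frames)) nrow(frames[[1]]) else 0L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  writeBin(charToRaw("CGTRJ1 units=angstrom,ns\n"), con)
  writeBin(c(length(frames), n), con, size = 4, endian = "little")
  writeBin(as.numeric(times_ns), con, size = 8, endian = "little")
  for (f in frames)
    writeBin(as.numeric(t(f)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a trajectory container
#' @param path file written by \code{\link{write_trajectory}}.
#' @return List with \code{frames} and \code{times_ns}.
#' @export
read_trajectory <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 25)
  if (!identical(rawToChar(hdr), "CGTRJ1 units=angstrom,ns\n"))
    stop("not a gophos trajectory container")
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  times <- readBin(con, "numeric", dims[1], size = 8, endian = "little")
  frames <- lapply(seq_len(dims[1]), function(k)
    matrix(readBin(con, "numeric", 3 * dims[2], size = 8, endian = "little"),
           dims[2], 3, byrow = TRUE))
  list(frames = frames, times_ns = times)
}
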