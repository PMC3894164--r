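# Experiment designs: conformation-randomization ensembles, iterative
# first-binding-event campaigns, charge-stripped variants, and
# phosphorylation-mimicking second-event campaigns.

#' Generate a conformation-randomization ensemble
#'
#' Removes all P-site attractive terms (which precludes stable
#' P-site/active-site interactions), runs independent trajectories from the
#' reference structure, and samples member structures at a fixed interval.
#' The default shape mirrors the production protocol: 5 trajectories of
#' 10 us sampled every 0.1 us, i.e. 500 members; tests use scaled-down
#' settings.
#'
#' @param topology a \code{cg_topology} with P-site groups.
#' @param ff a \code{go_forcefield}.
#' @param config a \code{bd_config}; the snapshot cadence is overridden by
#'   \code{sample_interval_us}.
#' @param n_trajectories independent randomization trajectories.
#' @param duration_us trajectory length, us.
#' @param sample_interval_us sampling interval, us.
#' @param seed base seed; trajectory k uses \code{seed + k}.
#' @param record_monitors record P-site trigger-contact counts in each
#'   sampled frame (audit that no stable docking occurs).
#' @return An \code{ensemble_set}: member coordinate matrices with
#'   provenance (source trajectory, sample time), generation settings, and
#'   the stripped-attractions flag.
#' @export
randomize_ensemble <- function(topology, ff, config = bd_config(),
                               n_trajectories = 5, duration_us = 10,
                               sample_interval_us = 0.1, seed = 1,
                               record_monitors = FALSE) {
  if (!length(topology$psite_groups))
    stop("topology has no P-site groups to strip")
  stripped <- strip_psite_attractions(topology)
  snap_ps <- sample_interval_us * 1e6
  cfg <- config
  cfg$steps[["snapshot"]] <- round(snap_ps / cfg$dt_ps)
  members <- list(); prov <- NULL; mon <- NULL
  monitors <- if (record_monitors)
    psite_monitors(stripped, only_enabled = FALSE,
                   force_nonterminating = TRUE) else FALSE
  for (k in seq_len(n_trajectories)) {
    tr <- run_dynamics(stripped, ff, cfg, duration_ns = duration_us * 1000,
                       seed = seed + k, monitors = monitors,
                       store_coords = TRUE,
                       record_monitors = record_monitors)
    keep <- which(tr$times_ns > 0)
    for (q in keep) {
      members <- c(members, list(tr$frames[[q]]))
      prov <- rbind(prov, data.frame(member = length(members), trajectory = k,
                                     time_us = tr$times_ns[q] / 1000))
    }
    if (record_monitors)
      mon <- rbind(mon, tr$monitor_counts[keep, , drop = FALSE])
  }
  if (length(members) < n_trajectories * floor(duration_us / sample_interval_us))
    warning("ensemble smaller than requested")
  structure(list(members = members, provenance = prov,
                 settings = list(n_trajectories = n_trajectories,
                                 duration_us = duration_us,
                                 sample_interval_us = sample_interval_us,
                                 seed = seed),
                 psite_stripped = TRUE, monitor_counts = mon),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "ensemble_set: %d members (%d trajectories x %g us @ %g us)%s\n",
    length(x$members), s$n_trajectories, s$duration_us,
    s$sample_interval_us,
    if (isTRUE(x$psite_stripped)) ", P-site attractions removed" else ""))
  invisible(x)
}

#' Run an iterative first-binding-event campaign
#'
#' Repeats: draw a starting structure uniformly (with replacement) from the
#' randomized ensemble, restore the P-site attractive terms, and propagate
#' until a stable P-site/catalytic-site interaction occurs (all trigger
#' contacts simultaneously formed) or the trial times out.  The elapsed
#' time and identity of the bound P-site are recorded per trial; timeouts
#' are reported separately and excluded from the frequency counts.
#'
#' @param topology a \code{cg_topology} (P-site attractions are restored
#'   before running).
#' @param ff a \code{go_forcefield}.
#' @param config a \code{bd_config}.
#' @param ensemble an \code{ensemble_set} (or a plain list of coordinate
#'   matrices).
#' @param n_trials number of trials.
#' @param seed campaign seed; per-trial seeds and start draws derive from
#'   it.
#' @param timeout_ns per-trial simulated-time bound, ns (default 5 us).
#' @param contact_gamma trigger-formation threshold multiplier.
#' @param keep_finals keep each trial's final coordinates (needed to seed
#'   second-event campaigns).
#' @return List with \code{records} (one row per trial), \code{table} (a
#'   \code{binding_event_table}) and optionally \code{finals}.
#' @export
run_binding_campaign <- function(topology, ff, config = bd_config(),
                                 ensemble, n_trials, seed = 1,
                                 timeout_ns = 5000, contact_gamma = 1.2,
                                 keep_finals = FALSE) {
  members <- if (inherits(ensemble, "ensemble_set")) ensemble$members
             else ensemble
  if (!length(members)) stop("ensemble is empty")
  prov <- if (inherits(ensemble, "ensemble_set")) ensemble$provenance
          else data.frame(member = seq_along(members), trajectory = NA,
                          time_us = NA)
  topology <- restore_psite_attractions(topology)
  monitors <- psite_monitors(topology, contact_gamma)
  if (!any(vapply(monitors, function(m) m$terminating, logical(1))))
    stop("no enabled productive P-site groups: nothing can terminate a trial")
  draws <- with_seed_(seed, list(
    start = sample.int(length(members), n_trials, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1, n_trials)))
  records <- NULL
  finals <- if (keep_finals) vector("list", n_trials) else NULL
  for (tr in seq_len(n_trials)) {
    res <- run_dynamics(topology, ff, config, duration_ns = timeout_ns,
                        seed = draws$seeds[tr],
                        coords = members[[draws$start[tr]]],
                        monitors = monitors, contact_gamma = contact_gamma)
    ev <- res$termination
    records <- rbind(records, data.frame(
      trial = tr, seed = draws$seeds[tr],
      site = if (ev$reason == "event") ev$site else NA_character_,
      chain = if (ev$reason == "event") ev$chain else NA_character_,
      cis = if (ev$reason == "event") ev$cis else NA,
      time_ns = ev$time_ns,
      structure_id = draws$start[tr],
      structure_trajectory = prov$trajectory[draws$start[tr]],
      structure_time_us = prov$time_us[draws$start[tr]],
      outcome = ev$reason, stringsAsFactors = FALSE))
    if (keep_finals) finals[[tr]] <- res$final
  }
  out <- list(records = records,
              table = binding_event_table(records))
  if (keep_finals) out$finals <- finals
  out
}

#' Tabulate binding events
#'
#' Aggregates per-trial event records into counts per (site, chain), cis and
#' trans totals per site, and campaign metadata (trials, productive events,
#' timeouts, total and mean simulated event time).
#'
#' @param records event records from \code{\link{run_binding_campaign}}.
#' @return A \code{binding_event_table}.
#' @export
binding_event_table <- function(records) {
  ev <- records[records$outcome == "event", , drop = FALSE]
  counts <- if (nrow(ev)) {
    ag <- aggregate(list(n = ev$trial), by = list(site = ev$site,
                                                  chain = ev$chain,
                                                  cis = ev$cis), FUN = length)
    ag[order(ag$site, ag$chain), ]
  } else data.frame(site = character(), chain = character(),
                    cis = logical(), n = integer())
  total_time <- sum(records$time_ns)
  meta <- list(n_trials = nrow(records), n_events = nrow(ev),
               n_timeouts = sum(records$outcome == "max-time"),
               total_time_ns = total_time,
               mean_event_time_ns = if (nrow(ev)) total_time / nrow(ev)
                                    else NA_real_)
  structure(list(counts = counts, meta = meta), class = "binding_event_table")
}

#' Per-site cis/trans/total counts of a binding-event table
#' @param table a \code{binding_event_table}.
#' @return data.frame with site, cis, trans and total columns.
#' @export
site_counts <- function(table) {
  ct <- table$counts
  sites <- sort(unique(ct$site))
  out <- data.frame(site = sites,
                    cis = vapply(sites, function(s)
                      sum(ct$n[ct$site == s & ct$cis]), numeric(1)),
                    trans = vapply(sites, function(s)
                      sum(ct$n[ct$site == s & !ct$cis]), numeric(1)))
  out$total <- out$cis + out$trans
  rownames(out) <- NULL
  out
}

#' @export
print.binding_event_table <- function(x, ...) {
  m <- x$meta
  cat(sprintf("binding_event_table: %d events / %d trials (%d timeouts)\n",
              m$n_events, m$n_trials, m$n_timeouts))
  cat(sprintf("  total simulated time %.3f us, mean event time %.3f us\n",
              m$total_time_ns / 1000, m$mean_event_time_ns / 1000))
  if (nrow(x$counts)) print(site_counts(x))
  invisible(x)
}

#' Zero the charges of C-terminal tail residues
#'
#' Sets the charge of every bead in the named residue ranges to zero while
#' leaving all attractive terms intact; used to isolate the role of tail
#' electrostatics in P-site capture.  Idempotent.
#'
#' @param topology a \code{cg_topology}.
#' @param ranges list of lists with \code{chain}, \code{first}, \code{last}.
#' @return Modified topology.
#' @export
zero_ct_charges <- function(topology, ranges) {
  b <- topology$beads
  for (r in ranges) {
    sel <- b$chain == r$chain & b$resno >= r$first & b$resno <= r$last &
      b$kind == "residue"
    topology$beads$charge[sel] <- 0
  }
  topology
}

#' Mimic the phosphorylation of a P-site
#'
#' Gives the target tyrosine bead a formal negative charge and removes every
#' native contact and short-range attractive potential involving the site's
#' nine window residues (productive and mirror copies), so the site can no
#' longer trigger a binding event.
#'
#' @param topology a \code{cg_topology}.
#' @param site P-site id (e.g. "992A").
#' @param phospho_charge charge increment of the tyrosine bead (default -1).
#' @return Modified topology.
#' @export
mimic_phosphorylation <- function(topology, site, phospho_charge = -1) {
  hits <- find_psite_group(topology, site)
  tyr <- topology$psite_groups[[hits[1]]]$tyr
  window <- topology$psite_groups[[hits[1]]]$window
  for (k in hits) {
    g <- topology$psite_groups[[k]]
    g$enabled <- FALSE
    g$removed <- TRUE
    topology$psite_groups[[k]] <- g
    topology$contacts$active[topology$contacts$tag == g$tag] <- FALSE
  }
  # any remaining attractive term touching the window residues
  touch <- topology$contacts$i %in% window | topology$contacts$j %in% window
  topology$contacts$active[touch] <- FALSE
  topology$beads$charge[tyr] <- topology$beads$charge[tyr] + phospho_charge
  topology
}

#' Run a second-binding-event campaign after a first phosphorylation
#'
#' Starting from bound-state structures of a first P-site (the final frames
#' of its binding events), mimics that site's phosphorylation
#' (\code{\link{mimic_phosphorylation}}) so each trial begins with the
#' release of the phosphorylated site from the catalytic site, then runs the
#' standard campaign loop until a second P-site binds.
#'
#' @param topology a \code{cg_topology}.
#' @param ff,config,n_trials,seed,timeout_ns,contact_gamma as in
#'   \code{\link{run_binding_campaign}}.
#' @param starts list of bound-state coordinate matrices for the first site.
#' @param first_site P-site id whose phosphorylation is mimicked.
#' @return As \code{\link{run_binding_campaign}}.
#' @export
run_second_event_campaign <- function(topology, ff, config = bd_config(),
                                      starts, first_site, n_trials, seed = 1,
                                      timeout_ns = 5000,
                                      contact_gamma = 1.2) {
  topology <- restore_psite_attractions(topology)
  topology <- mimic_phosphorylation(topology, first_site)
  run_binding_campaign(topology, ff, config, starts, n_trials, seed,
                       timeout_ns, contact_gamma)
}

#' Segment nonproductive activator-site binding episodes
#'
#' Identifies binding episodes from a distance trace between a P-site
#' tyrosine and the activator active-site anchor (the catalytic aspartate
#' bead): an episode opens when the distance stays at or below the
#' threshold (about 12 A, the closest-approach distance) for at least the
#' dwell time, tolerates excursions shorter than the dwell, and closes on a
#' sustained exit.
#'
#' @param times_ns sample times, ns (strictly increasing).
#' @param distances numeric vector (one trace) or matrix with one column per
#'   monitored site.
#' @param threshold_A episode distance threshold, A.
#' @param dwell_ns minimum dwell (and minimum exit) duration, ns.
#' @param sites optional site labels for matrix input.
#' @return data.frame with columns site, entry_ns, exit_ns (exit NA when the
#'   trace ends inside an episode).
#' @export
monitor_nonproductive_binding <- function(times_ns, distances,
                                          threshold_A = 12, dwell_ns = 1,
                                          sites = NULL) {
  if (is.null(dim(distances))) distances <- matrix(distances, ncol = 1)
  if (is.null(sites)) sites <- colnames(distances) %||%
      paste0("site", seq_len(ncol(distances)))
  out <- NULL
  for (cc in seq_len(ncol(distances))) {
    below <- distances[, cc] <= threshold_A
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    open <- FALSE; entry <- NA_real_; last_below_end <- NA_real_
    for (q in seq_along(r$values)) {
      t0 <- times_ns[starts[q]]
      t1 <- times_ns[ends[q]]
      dur <- t1 - t0
      if (r$values[q]) {
        if (!open && dur >= dwell_ns) { open <- TRUE; entry <- t0 }
        if (open) last_below_end <- t1
      } else if (open && dur >= dwell_ns) {
        out <- rbind(out, data.frame(site = sites[cc], entry_ns = entry,
                                     exit_ns = t0))
        open <- FALSE
      }
    }
    if (open) out <- rbind(out, data.frame(site = sites[cc], entry_ns = entry,
                                           exit_ns = NA_real_))
  }
  if (is.null(out)) out <- data.frame(site = character(),
                                      entry_ns = numeric(),
                                      exit_ns = numeric())
  rownames(out) <- NULL
  out
}
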