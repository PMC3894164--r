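# Statistics and derived quantities: exact multinomial tests, proximity
# censuses, distance distributions, v_phos prediction, and the
# initial-structure correlation audit.

#' Exact multinomial goodness-of-fit test
#'
#' Tests observed category counts against an equiprobable multinomial null.
#' With two categories the test reduces to the exact two-sided binomial
#' (p = sum of the probabilities of all outcomes no more likely than the
#' observed one).  With more categories the null distribution of the table
#' probability is enumerated exactly when feasible, otherwise estimated by
#' seeded Monte Carlo with at least 1e5 draws (the standard error of the
#' p-value is reported).
#'
#' @param counts nonnegative integer counts, length >= 2.
#' @param n_mc Monte Carlo draws when enumeration is infeasible.
#' @param max_enum largest number of compositions enumerated exactly.
#' @param seed Monte Carlo seed.
#' @return List with \code{p.value}, \code{method}, and \code{se} (NA for
#'   exact branches).
#' @export
multinomial_test <- function(counts, n_mc = 1e5, max_enum = 2e5, seed = 1) {
  counts <- as.integer(counts)
  if (length(counts) < 2) stop("need at least two categories")
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) stop("all-zero counts: test undefined")
  k <- length(counts)
  tol <- 1e-9
  if (k == 2) {
    probs <- dbinom(0:n, n, 0.5)
    p <- sum(probs[probs <= dbinom(counts[1], n, 0.5) * (1 + tol)])
    return(list(p.value = min(1, p), method = "exact binomial (two-sided)",
                se = NA_real_))
  }
  p_obs <- dmultinom(counts, prob = rep(1 / k, k))
  n_comp <- choose(n + k - 1, k - 1)
  if (n_comp <= max_enum) {
    p <- 0
    # enumerate all compositions of n into k parts
    comp <- integer(k)
    rec <- function(pos, rem) {
      if (pos == k) {
        comp[k] <<- rem
        pr <- dmultinom(comp, prob = rep(1 / k, k))
        if (pr <= p_obs * (1 + tol)) p <<- p + pr
        return(invisible())
      }
      for (v in 0:rem) {
        comp[pos] <<- v
        rec(pos + 1, rem - v)
      }
    }
    rec(1, n)
    return(list(p.value = min(1, p), method = "exact multinomial enumeration",
                se = NA_real_))
  }
  hits <- with_seed_(seed, {
    draws <- rmultinom(n_mc, n, rep(1 / k, k))
    pr <- apply(draws, 2, dmultinom, prob = rep(1 / k, k))
    sum(pr <= p_obs * (1 + tol))
  })
  p <- hits / n_mc
  list(p.value = p, method = sprintf("Monte Carlo multinomial (%g draws)",
                                     n_mc),
       se = sqrt(p * (1 - p) / n_mc))
}

#' Cis/trans (or per-site) binding-frequency significance test
#'
#' Convenience wrapper around \code{\link{multinomial_test}} for comparing
#' binding-event frequencies across categories (e.g. cis vs trans totals,
#' or per-site counts).
#'
#' @inheritParams multinomial_test
#' @return See \code{\link{multinomial_test}}.
#' @examples
#' cis_trans_test(c(253, 167))$p.value   # < 1e-4
#' cis_trans_test(c(50, 50))$p.value     # exactly 1
#' @export
cis_trans_test <- function(counts, n_mc = 1e5, seed = 1)
  multinomial_test(counts, n_mc = n_mc, seed = seed)

#' Census of P-sites near the catalytic site
#'
#' For every ensemble member, counts whether each P-site tyrosine bead lies
#' within a closed ball of the given radius around the anchor bead (by
#' convention the gamma-phosphate of the bound nucleotide; distances equal
#' to the radius are included).
#'
#' @param ensemble an \code{ensemble_set} or list of coordinate matrices.
#' @param topology the shared \code{cg_topology}.
#' @param anchor anchor bead index (default: the receiver gamma-phosphate
#'   bead from the topology's catalytic metadata).
#' @param radius_A ball radius, A.
#' @return data.frame with site, chain, cis and count (members with the
#'   tyrosine inside the ball).
#' @export
proximity_census <- function(ensemble, topology, anchor = NULL,
                             radius_A = 40) {
  members <- if (inherits(ensemble, "ensemble_set")) ensemble$members
             else ensemble
  if (is.null(anchor)) {
    rc <- topology$catalytic$receiver
    anchor <- topology$catalytic[[rc]]$gamma
  }
  groups <- Filter(function(g) g$role == "productive", topology$psite_groups)
  out <- data.frame(
    site = vapply(groups, `[[`, character(1), "site"),
    chain = vapply(groups, `[[`, character(1), "chain"),
    cis = vapply(groups, `[[`, logical(1), "cis"))
  out$count <- vapply(groups, function(g) {
    sum(vapply(members, function(m)
      sqrt(sum((m[g$tyr, ] - m[anchor, ])^2)) <= radius_A, logical(1)))
  }, numeric(1))
  out
}

#' P-site/anchor distance distributions over an ensemble
#'
#' Collects, for each P-site tyrosine, its distance to the given anchor
#' bead in every ensemble member; returns the samples, binned densities,
#' and the subset of members within \code{subset_radius_A} (closed ball)
#' for structure-gallery export.
#'
#' @param ensemble an \code{ensemble_set} or list of coordinate matrices.
#' @param topology the shared \code{cg_topology}.
#' @param anchor anchor bead index (default: receiver gamma-phosphate).
#' @param breaks histogram breaks (A) or a break count.
#' @param subset_radius_A radius of the reported subset, A.
#' @return List with \code{samples} (long data.frame), \code{histograms}
#'   (per site) and \code{subset} (member indices per site within the
#'   radius).
#' @export
distance_distributions <- function(ensemble, topology, anchor = NULL,
                                   breaks = 30, subset_radius_A = 30) {
  members <- if (inherits(ensemble, "ensemble_set")) ensemble$members
             else ensemble
  if (is.null(anchor)) {
    rc <- topology$catalytic$receiver
    anchor <- topology$catalytic[[rc]]$gamma
  }
  groups <- Filter(function(g) g$role == "productive", topology$psite_groups)
  samples <- do.call(rbind, lapply(groups, function(g) {
    d <- vapply(members, function(m)
      sqrt(sum((m[g$tyr, ] - m[anchor, ])^2)), numeric(1))
    data.frame(site = g$site, chain = g$chain, member = seq_along(members),
               distance_A = d)
  }))
  hists <- lapply(split(samples$distance_A, samples$site),
                  function(d) hist(d, breaks = breaks, plot = FALSE))
  subset <- lapply(split(samples, samples$site), function(df)
    df$member[df$distance_A <= subset_radius_A])
  list(samples = samples, histograms = hists, subset = subset)
}

#' Packaged P-site peptide kinetics table
#'
#' Steady-state catalytic efficiencies kcat/KM (mM^-1 min^-1) for synthetic
#' peptides spanning the receptor's C-terminal P-site sequences, together
#' with the reported relative self-phosphorylation velocities used for
#' consistency checks.  Missing values mark sites without measured peptide
#' kinetics.
#'
#' @return data.frame with columns site, sequence, category, kcat_km,
#'   vphos_reported.
#' @export
psite_kinetics <- function() {
  path <- system.file("extdata", "psite_kinetics.tsv", package = "gophos")
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(site = "character"))
}

#' Predict relative P-site phosphorylation velocities
#'
#' Combines relative catalytic-site binding frequencies with peptide
#' catalytic efficiencies: \code{v_phos = k_intra * (kcat/KM)}, where
#' \code{k_intra} is each site's relative binding frequency (receiver and
#' activator copies summed) from campaigns run without tail electrostatics.
#' \code{v_phos} is a relative quantity: uniform rescaling of the
#' frequencies rescales all values but preserves their ratios.
#'
#' @param frequencies named numeric vector of per-site binding counts (or
#'   already-relative frequencies), names matching the kinetics table's
#'   site column; alternatively a \code{binding_event_table}.
#' @param kinetics kinetics data.frame (default \code{\link{psite_kinetics}}).
#' @param normalize \code{"sum"} scales frequencies to sum to one;
#'   \code{"none"} uses them as given.
#' @param stripped_flag when a \code{binding_event_table} from a campaign
#'   with tail charges intact is supplied, a warning reminds that the
#'   prediction assumes charge-stripped frequencies.
#' @return data.frame with site, k_intra, kcat_km and vphos (NA where
#'   kinetics are missing).
#' @export
predict_vphos <- function(frequencies, kinetics = psite_kinetics(),
                          normalize = c("sum", "none"),
                          stripped_flag = NA) {
  normalize <- match.arg(normalize)
  if (inherits(frequencies, "binding_event_table")) {
    sc <- site_counts(frequencies)
    frequencies <- setNames(sc$total, sc$site)
  }
  if (is.null(names(frequencies)))
    stop("frequencies must be named by site")
  if (any(frequencies < 0)) stop("frequencies must be nonnegative")
  if (isFALSE(stripped_flag))
    warning("frequencies come from a campaign with tail electrostatics; ",
            "v_phos assumes charge-stripped binding frequencies")
  k_intra <- if (normalize == "sum") frequencies / sum(frequencies)
             else frequencies
  kk <- kinetics$kcat_km[match(names(frequencies), kinetics$site)]
  out <- data.frame(site = names(frequencies), k_intra = as.numeric(k_intra),
                    kcat_km = kk, vphos = as.numeric(k_intra) * kk)
  rownames(out) <- NULL
  out
}

#' Initial-structure correlation audit
#'
#' Checks whether trials started from structures sampled close together in
#' randomization-trajectory time are over-represented among same-site
#' binding events.  For every pair of same-site events whose initial
#' structures came from the same trajectory, the sample-time gap dt is
#' compared against the triangular null density p(dt) = (2/T)(1 - dt/T) of
#' gaps between two times drawn uniformly from [0, T].
#'
#' @param records event records with provenance columns
#'   \code{structure_trajectory} and \code{structure_time_us}.
#' @param T_us randomization-trajectory span, us.
#' @param n_bins histogram bins over [0, T].
#' @return A \code{correlation_audit}: the gap samples, observed and
#'   expected bin counts, and the per-bin excess.
#' @export
correlation_audit <- function(records, T_us, n_bins = 10) {
  ev <- records[records$outcome == "event" & !is.na(records$site), ,
                drop = FALSE]
  gaps <- numeric(0)
  if (nrow(ev) > 1) {
    for (s in unique(ev$site)) {
      sub <- ev[ev$site == s, , drop = FALSE]
      if (nrow(sub) < 2) next
      for (a in seq_len(nrow(sub) - 1)) for (b in (a + 1):nrow(sub)) {
        if (!is.na(sub$structure_trajectory[a]) &&
            identical(sub$structure_trajectory[a],
                      sub$structure_trajectory[b]))
          gaps <- c(gaps, abs(sub$structure_time_us[a] -
                              sub$structure_time_us[b]))
      }
    }
  }
  breaks <- seq(0, T_us, length.out = n_bins + 1)
  observed <- if (length(gaps)) hist(gaps, breaks = breaks,
                                     plot = FALSE)$counts
              else integer(n_bins)
  # expected fraction per bin under the triangular null
  cdf <- function(x) (2 * x / T_us) - (x / T_us)^2
  expected <- length(gaps) * diff(cdf(breaks))
  structure(list(gaps_us = gaps, breaks_us = breaks, observed = observed,
                 expected = expected, excess = observed - expected,
                 T_us = T_us, n_pairs = length(gaps)),
            class = "correlation_audit")
}

#' Triangular null density of uniform time gaps
#' @param dt gap values.
#' @param T_us total interval.
#' @return Density values (2/T)(1 - dt/T), zero outside [0, T].
#' @export
gap_null_density <- function(dt, T_us)
  ifelse(dt >= 0 & dt <= T_us, (2 / T_us) * (1 - dt / T_us), 0)

#' @export
print.correlation_audit <- function(x, ...) {
  cat(sprintf("correlation_audit: %d same-site/same-trajectory event pairs over T = %g us\n",
              x$n_pairs, x$T_us))
  if (x$n_pairs == 0) {
    cat("  all events from distinct trajectories: nothing to audit\n")
  } else {
    df <- data.frame(bin = sprintf("[%.2f,%.2f)", head(x$breaks_us, -1),
                                   tail(x$breaks_us, -1)),
                     observed = x$observed,
                     expected = round(x$expected, 2),
                     excess = round(x$excess, 2))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a binding-event campaign
#'
#' Totals, cis/trans sums, per-site sums, mean event time, the cis-vs-trans
#' significance test, and the same test with one site excluded (e.g. to ask
#' whether an exceptional site alone drives a cis/trans bias).
#'
#' @param table a \code{binding_event_table}.
#' @param exclude_site optional site id excluded from a second cis/trans
#'   test.
#' @return List with counts, totals, \code{mean_event_time_ns},
#'   \code{cis_trans_p} and optionally \code{cis_trans_p_excluding}.
#' @export
summarize_campaign <- function(table, exclude_site = NULL) {
  sc <- site_counts(table)
  cis <- sum(sc$cis); trans <- sum(sc$trans)
  out <- list(site_counts = sc, n_events = table$meta$n_events,
              n_trials = table$meta$n_trials,
              n_timeouts = table$meta$n_timeouts,
              cis_total = cis, trans_total = trans,
              total_time_ns = table$meta$total_time_ns,
              mean_event_time_ns = table$meta$mean_event_time_ns,
              cis_trans_p = if (cis + trans > 0)
                cis_trans_test(c(cis, trans))$p.value else NA_real_)
  if (!is.null(exclude_site)) {
    keep <- sc[sc$site != exclude_site, , drop = FALSE]
    out$cis_trans_p_excluding <-
      if (sum(keep$cis, keep$trans) > 0)
        cis_trans_test(c(sum(keep$cis), sum(keep$trans)))$p.value
      else NA_real_
  }
  out
}

#' Mean binding-event time from campaign totals
#'
#' @param total_time total simulated time (any unit).
#' @param n_events number of productive binding events.
#' @return Mean time per event, same unit.
#' @examples
#' round(mean_event_time(193, 420), 2)   # 0.46 us per event
#' @export
mean_event_time <- function(total_time, n_events) {
  if (n_events <= 0) stop("no events")
  total_time / n_events
}
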