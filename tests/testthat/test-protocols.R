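# A small single-site toy shared by the protocol tests.
small_toy <- make_toy_dimer(toy_dimer_spec(tethers = list(A = 10, B = 10),
                                           seed = 21))

test_that("randomization ensembles count, strip and reproduce", {
  ens <- randomize_ensemble(small_toy, ff0, cfg_toy(), n_trajectories = 2,
                            duration_us = 0.002, sample_interval_us = 5e-4,
                            seed = 9, record_monitors = TRUE)
  expect_s3_class(ens, "ensemble_set")
  expect_equal(length(ens$members), 8)         # 2 x (2 ns / 0.5 ns)
  expect_true(ens$psite_stripped)
  expect_equal(unique(ens$provenance$trajectory), 1:2)
  expect_false(any(duplicated(
    ens$provenance[, c("trajectory", "time_us")])))
  # no frame forms a full trigger while attractions are stripped
  expect_true(max(ens$monitor_counts) <
              small_toy$psite_groups[[1]]$trigger)
  ens2 <- randomize_ensemble(small_toy, ff0, cfg_toy(), n_trajectories = 2,
                             duration_us = 0.002, sample_interval_us = 5e-4,
                             seed = 9)
  expect_identical(ens$members, ens2$members)
  expect_error(randomize_ensemble(mk_chain_top(random_chain_xyz(5, 1)),
                                  ff0, cfg_toy()),
               "no P-site groups")
})

test_that("campaigns conserve trials and record consistent events", {
  ens <- randomize_ensemble(small_toy, ff0, cfg_toy(), n_trajectories = 2,
                            duration_us = 0.004, sample_interval_us = 1e-3,
                            seed = 3)
  camp <- run_binding_campaign(small_toy, ff0, cfg_toy(), ens, n_trials = 8,
                               seed = 5, timeout_ns = 3)
  rec <- camp$records
  expect_equal(nrow(rec), 8)
  expect_equal(sum(rec$outcome == "event") + sum(rec$outcome == "max-time"),
               8)
  expect_true(all(rec$time_ns > 0 & rec$time_ns <= 3 + 1e-9))
  tab <- camp$table
  expect_equal(sum(tab$counts$n), tab$meta$n_events)
  expect_equal(tab$meta$mean_event_time_ns,
               tab$meta$total_time_ns / tab$meta$n_events)
  # cis flag consistent with the chain id (receiver is chain A)
  ev <- rec[rec$outcome == "event", ]
  expect_identical(ev$cis, ev$chain == "A")
  # determinism under the campaign seed
  camp2 <- run_binding_campaign(small_toy, ff0, cfg_toy(), ens, n_trials = 8,
                                seed = 5, timeout_ns = 3)
  expect_identical(camp$records, camp2$records)
  expect_error(run_binding_campaign(small_toy, ff0, cfg_toy(),
                                    list(), n_trials = 2, seed = 1),
               "empty")
})

test_that("tail charge zeroing is targeted and idempotent", {
  top <- small_toy
  tails <- lapply(c("A", "B"), function(ch) {
    b <- top$beads
    list(chain = ch,
         first = min(b$resno[b$chain == ch & b$region == "modeled" &
                             b$resno > 20]),
         last = max(b$resno[b$chain == ch]))
  })
  z <- zero_ct_charges(top, tails)
  b <- z$beads
  for (r in tails)
    expect_equal(sum(abs(b$charge[b$chain == r$chain &
                                  b$resno >= r$first])), 0)
  # non-tail charges untouched (the patch decoration)
  expect_equal(b$charge[top$catalytic$A$patch],
               top$beads$charge[top$catalytic$A$patch])
  expect_identical(zero_ct_charges(z, tails), z)
})

test_that("mimicking phosphorylation disables the site and charges the tyrosine", {
  top <- restore_psite_attractions(small_toy)
  g <- top$psite_groups[[gophos:::find_psite_group(top, "t10A",
                                                   "productive")]]
  ph <- mimic_phosphorylation(top, "t10A")
  expect_equal(ph$beads$charge[g$tyr], top$beads$charge[g$tyr] - 1)
  idx <- gophos:::find_psite_group(ph, "t10A")
  for (k in idx) {
    expect_false(ph$psite_groups[[k]]$enabled)
    expect_true(ph$psite_groups[[k]]$removed)
  }
  # no active attractive term touches the nine window residues
  act <- gophos:::active_contacts(ph)
  expect_false(any(act$i %in% g$window | act$j %in% g$window))
  # other sites' groups unchanged
  other <- gophos:::find_psite_group(ph, "t10B")
  for (k in other) expect_true(ph$psite_groups[[k]]$enabled)
  # restoring does not resurrect a removed site
  expect_false(restore_psite_attractions(ph)$psite_groups[[idx[1]]]$enabled)
  expect_error(mimic_phosphorylation(top, "nope"), "unknown P-site")
})

test_that("second-event campaigns start from bound states and exclude the first site", {
  pre <- make_toy_dimer(toy_dimer_spec(tethers = list(A = c(10, 20),
                                                      B = c(10, 20)),
                                       predock = "t10A", seed = 11))
  camp2 <- run_second_event_campaign(pre, ff0, cfg_toy(),
                                     starts = list(pre$coords),
                                     first_site = "t10A", n_trials = 6,
                                     seed = 8, timeout_ns = 4)
  rec <- camp2$records
  expect_equal(nrow(rec), 6)
  expect_false(any(rec$site == "t10A", na.rm = TRUE))
  expect_equal(sum(camp2$table$counts$n),
               sum(rec$outcome == "event"))
})

test_that("nonproductive binding episodes are segmented with a dwell filter", {
  t <- seq(0, 20, by = 0.1)
  # one clean episode: dip to 11 A for 2 ns
  d1 <- ifelse(t >= 5 & t <= 7, 11, 20)
  ep <- monitor_nonproductive_binding(t, d1, threshold_A = 12, dwell_ns = 1)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$entry_ns, 5)
  expect_equal(ep$exit_ns, 7.1, tolerance = 0.11)
  # oscillation faster than the dwell: no episode
  d2 <- ifelse(floor(t * 2) %% 2 == 0, 11, 14)
  expect_equal(nrow(monitor_nonproductive_binding(t, d2, 12, 1)), 0)
  # two separated plateaus -> two ordered episodes
  d3 <- ifelse((t >= 2 & t <= 5) | (t >= 10 & t <= 14), 11.5, 18)
  ep3 <- monitor_nonproductive_binding(t, d3, 12, 1)
  expect_equal(nrow(ep3), 2)
  expect_equal(ep3$entry_ns, c(2, 10))
  expect_true(all(diff(ep3$entry_ns) > 0))
  # brief excursions inside an episode do not close it
  d4 <- ifelse(t >= 3 & t <= 9, 11, 20); d4[t > 5.9 & t < 6.3] <- 14
  expect_equal(nrow(monitor_nonproductive_binding(t, d4, 12, 1)), 1)
})
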