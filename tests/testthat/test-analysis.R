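test_that("the exact binomial branch reproduces known significance levels", {
  expect_lt(cis_trans_test(c(253, 167))$p.value, 1e-4)
  expect_lt(cis_trans_test(c(138, 54))$p.value, 0.05)
  expect_equal(cis_trans_test(c(50, 50))$p.value, 1)
  # independent cross-check of the hand-rolled branch against stats::binom.test
  for (cts in list(c(253, 167), c(138, 54), c(30, 12), c(7, 7)))
    expect_equal(multinomial_test(cts)$p.value,
                 stats::binom.test(cts[1], sum(cts), 0.5)$p.value,
                 tolerance = 1e-12)
  expect_error(multinomial_test(c(0, 0)), "undefined")
  expect_error(multinomial_test(5), "two categories")
})

test_that("enumeration and Monte-Carlo multinomial branches agree", {
  cts <- c(9, 3, 1)
  ex <- multinomial_test(cts)
  expect_match(ex$method, "enumeration")
  mc <- multinomial_test(cts, max_enum = 1, n_mc = 2e4, seed = 2)
  expect_match(mc$method, "Monte Carlo")
  expect_false(is.na(mc$se))
  expect_lt(abs(mc$p.value - ex$p.value), 3 * mc$se + 1e-3)
  # symmetric tables are not significant
  expect_gt(multinomial_test(c(5, 5, 5))$p.value, 0.99)
})

test_that("proximity census equals a brute-force scan with a closed ball", {
  top <- make_toy_dimer(toy_dimer_spec(tethers = list(A = 10, B = 10),
                                       seed = 13))
  members <- gophos:::with_seed_(4, lapply(1:20, function(k)
    top$coords + matrix(rnorm(length(top$coords), sd = 6),
                        nrow(top$coords), 3)))
  cen <- proximity_census(members, top, radius_A = 40)
  anchor <- top$catalytic$A$gamma
  groups <- Filter(function(g) g$role == "productive", top$psite_groups)
  for (q in seq_along(groups)) {
    want <- sum(vapply(members, function(m)
      sqrt(sum((m[groups[[q]]$tyr, ] - m[anchor, ])^2)) <= 40, logical(1)))
    expect_equal(cen$count[cen$site == groups[[q]]$site &
                           cen$chain == groups[[q]]$chain], want)
  }
  # boundary convention: a tyrosine at exactly the radius is included
  m0 <- top$coords
  g <- groups[[1]]
  dir <- m0[g$tyr, ] - m0[anchor, ]
  m0[g$tyr, ] <- m0[anchor, ] + dir / sqrt(sum(dir^2)) * 40
  cen0 <- proximity_census(list(m0), top, radius_A = 40)
  expect_equal(cen0$count[cen0$site == g$site & cen0$chain == g$chain], 1)
  # empty ensemble: all-zero counts
  expect_true(all(proximity_census(list(), top)$count == 0))
})

test_that("distance distributions tabulate and subset correctly", {
  top <- make_toy_dimer(toy_dimer_spec(tethers = list(A = 10, B = 10),
                                       seed = 13))
  members <- gophos:::with_seed_(8, lapply(1:15, function(k)
    top$coords + matrix(rnorm(length(top$coords), sd = 5),
                        nrow(top$coords), 3)))
  dd <- distance_distributions(members, top, subset_radius_A = 30)
  expect_equal(nrow(dd$samples), 15 * 2)   # one productive site per chain
  for (s in names(dd$subset)) {
    sub <- dd$samples[dd$samples$site == s, ]
    expect_equal(sort(dd$subset[[s]]), sort(sub$member[sub$distance_A <= 30]))
  }
  for (h in dd$histograms) expect_equal(sum(h$counts), 15)
  # all-equal distances land in a single bin
  one <- distance_distributions(list(top$coords, top$coords), top,
                                breaks = 5)
  for (h in one$histograms) expect_equal(sum(h$counts > 0), 1)
})

test_that("v_phos predictions combine frequencies with peptide kinetics", {
  kin <- psite_kinetics()
  expect_equal(nrow(kin), 8)
  expect_true(all(kin$kcat_km > 0, na.rm = TRUE))
  with_k <- kin[!is.na(kin$kcat_km), ]
  # uniform frequencies: the v_phos ordering equals the kcat/KM ordering
  freqs <- setNames(rep(10, nrow(with_k)), with_k$site)
  vp <- predict_vphos(freqs, kin)
  expect_equal(order(vp$vphos), order(vp$kcat_km))
  # consistency inversion of the packaged table round-trips to 1 d.p.
  k_intra <- with_k$vphos_reported / with_k$kcat_km
  vp2 <- predict_vphos(setNames(k_intra, with_k$site), kin,
                       normalize = "none")
  expect_equal(round(vp2$vphos, 1), with_k$vphos_reported)
  # scale invariance of the ratios
  vp3 <- predict_vphos(freqs * 2, kin)
  expect_equal(vp3$vphos / vp$vphos, rep(1, nrow(vp)), tolerance = 1e-12)
  # sites without kinetics are flagged missing
  vp4 <- predict_vphos(c(`992` = 5, `1045` = 3), kin)
  expect_true(is.na(vp4$vphos[vp4$site == "1045"]))
})

test_that("the correlation audit matches the triangular null for uniform pairs", {
  T_us <- 10
  n_pairs <- 10000
  recs <- gophos:::with_seed_(12, {
    data.frame(trial = seq_len(2 * n_pairs),
               site = rep(paste0("s", seq_len(n_pairs)), each = 2),
               outcome = "event",
               structure_trajectory = rep(1L, 2 * n_pairs),
               structure_time_us = runif(2 * n_pairs, 0, T_us))
  })
  aud <- correlation_audit(recs, T_us, n_bins = 10)
  expect_equal(aud$n_pairs, n_pairs)
  chi2 <- sum((aud$observed - aud$expected)^2 / aud$expected)
  expect_lt(chi2, qchisq(0.99, df = 9))
  # null density: 2/T at zero gap, zero at dt = T, integrates to one
  expect_equal(gap_null_density(0, T_us), 2 / T_us)
  expect_equal(gap_null_density(T_us, T_us), 0)
  expect_equal(integrate(gap_null_density, 0, T_us, T_us = T_us)$value, 1,
               tolerance = 1e-6)
  # events from distinct trajectories leave nothing to audit
  recs$structure_trajectory <- seq_len(nrow(recs))
  empty <- correlation_audit(recs, T_us)
  expect_equal(empty$n_pairs, 0)
})

test_that("campaign summaries recompute totals, means and exclusion tests", {
  rec <- data.frame(
    trial = 1:12, seed = 1:12,
    site = c(rep("t10A", 6), rep("t60A", 2), rep("t60B", 3), NA),
    chain = c(rep("A", 8), rep("B", 3), NA),
    cis = c(rep(TRUE, 8), rep(FALSE, 3), NA),
    time_ns = rep(2, 12), structure_id = 1,
    outcome = c(rep("event", 11), "max-time"), stringsAsFactors = FALSE)
  tab <- binding_event_table(rec)
  s <- summarize_campaign(tab, exclude_site = "t10A")
  expect_equal(s$cis_total + s$trans_total, s$n_events)
  expect_equal(s$cis_total, 8)
  expect_equal(s$mean_event_time_ns, 24 / 11)
  expect_equal(s$cis_trans_p, cis_trans_test(c(8, 3))$p.value)
  expect_equal(s$cis_trans_p_excluding, cis_trans_test(c(2, 3))$p.value)
  # the printed-scale arithmetic: 193 us over 420 events -> 0.46 us
  expect_equal(round(mean_event_time(193, 420), 2), 0.46)
})
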