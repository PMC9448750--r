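test_that("biological profiles are multinomial draws from the mixture", {
  sigs <- mixture_basis()
  expect_error(synth_biological_profile(total = 0, seed = 1), "positive")
  # point-mass signature puts every mutation in one channel
  pm <- matrix(0, 96, 1, dimnames = list(channel_labels(), "point"))
  pm[17, 1] <- 1
  ct <- synth_biological_profile(pm, c(point = 1), total = 500, seed = 1)
  expect_equal(unname(ct$counts[17]), 500)
  expect_equal(total(ct), 500)
  # law of large numbers: empirical frequencies approach the mixture
  acts <- c(SBS1like = 0.25, SBS5like = 0.55, SBS18like = 0.2)
  p <- as.numeric(sigs %*% acts)
  big <- synth_biological_profile(sigs, acts, total = 1e6, seed = 2)
  expect_lt(max(abs(big$counts / 1e6 - p)), 0.005)
  # generating parameters are recorded
  expect_equal(big$metadata$activities, acts)
})

test_that("Poisson artefact injection has the right moments and conserves counts", {
  bio <- synth_biological_profile(total = 5000, seed = 3)
  # integer conservation before channel dropping
  smp <- add_ffpe_noise(bio, "unrepaired", 2000, seed = 4, drop_TC = FALSE)
  expect_equal(smp$observed$counts - smp$noise$counts, bio$counts)
  # with drop_TC the non-T>C channels still reconcile
  smp2 <- add_ffpe_noise(bio, "unrepaired", 2000, seed = 4)
  ntc <- channel_mask("NON_TC")
  expect_equal(smp2$observed$counts[ntc] - smp2$noise$counts[ntc],
               bio$counts[ntc])
  expect_true(all(smp2$observed$counts[channel_mask("TC")] == 0))
  # point-mass signature: injected count has Poisson mean/sd over replicates
  pm <- numeric(96); pm[33] <- 1
  sig <- ffpe_signature(pm, "unrepaired")
  draws <- vapply(1:200, function(s)
    add_ffpe_noise(bio, sig, 1e4, seed = s)$noise$counts[33], numeric(1))
  expect_equal(mean(draws), 1e4, tolerance = 0.005)
  expect_equal(sd(draws), 100, tolerance = 0.15)
  # total injected count has mean noise_total (sum of Poissons)
  totals <- vapply(1:200, function(s)
    sum(add_ffpe_noise(bio, "unrepaired", 5000, seed = s)$noise$counts),
    numeric(1))
  expect_equal(mean(totals), 5000, tolerance = 0.01)
  # and variance matching a single Poisson(noise_total) total: the
  # per-channel and total-then-multinomial formulations are equivalent
  expect_equal(var(totals), 5000, tolerance = 0.25)
  expect_error(add_ffpe_noise(bio, "unrepaired", -5), ">= 0")
})

test_that("SNR and SNS follow their definitions and scaling laws", {
  bio <- synth_biological_profile(total = 10000, seed = 5)
  ctb <- sum(bio$counts[channel_mask("CT")])
  expect_equal(compute_snr(bio, 1e4), ctb / 1e4)
  expect_true(is.na(compute_snr(bio, 0)))
  w1 <- bundled_signatures("unrepaired")
  # proportional C>T content gives SNS 1; disjoint support gives 0
  prop <- numeric(96); prop[channel_mask("CT")] <- w1$probabilities[channel_mask("CT")] * 3
  expect_equal(compute_sns(prop, w1), 1)
  # SNS is scale-invariant, SNR scales linearly
  expect_equal(compute_sns(3L * bio$counts, w1), compute_sns(bio$counts, w1))
  expect_equal(compute_snr(3 * bio$counts, 1e4), 3 * compute_snr(bio$counts, 1e4))
  # no C>T signal: undefined sentinel
  noct <- numeric(96); noct[1] <- 10
  expect_true(is.na(compute_sns(noct, w1)))
  # CpG-concentrated biology resembles the repaired artefact more than the
  # unrepaired one (the pancreatic-adenocarcinoma pattern)
  cpg_bio <- numeric(96)
  cpg_bio[c(35, 39, 43, 47)] <- c(80, 60, 50, 600)  # N[C>T]G spikes
  cpg_bio[1:16] <- 20
  expect_gt(compute_sns(cpg_bio, bundled_signatures("repaired")),
            compute_sns(cpg_bio, bundled_signatures("unrepaired")))
})

test_that("correction evaluation applies the strict well-corrected cutoff", {
  bio <- synth_biological_profile(total = 20000, seed = 6)
  smp <- add_ffpe_noise(bio, "unrepaired", 5000, seed = 7)
  fit <- ffpe_correct(smp$observed, "unrepaired",
                      control = correction_control(n_restarts = 4), seed = 1)
  ev <- evaluate_correction(smp, fit)
  expect_true(ev$accuracy > 0 && ev$accuracy <= 1)
  # threshold equal to the achieved accuracy: strictly greater fails
  ev_b <- evaluate_correction(smp, fit, threshold = ev$accuracy)
  expect_false(ev_b$well_corrected)
  # corrected == bio gives accuracy 1
  perfect <- fit
  perfect$corrected <- bio$counts
  expect_equal(evaluate_correction(smp, perfect)$accuracy, 1)
})

test_that("cohort simulation is reproducible and benchmark bins by C>T load", {
  co1 <- simulate_cohort(6, noise_total = 3000, seed = 99,
                         total_range = c(5e3, 2e4))
  co2 <- simulate_cohort(6, noise_total = 3000, seed = 99,
                         total_range = c(5e3, 2e4))
  expect_identical(lapply(co1, function(s) s$observed$counts),
                   lapply(co2, function(s) s$observed$counts))
  expect_identical(length(unique(vapply(co1, function(s) s$bio$sample_id,
                                        character(1)))), 6L)
  bench <- benchmark_cohort(co1, control = correction_control(n_restarts = 3),
                            seed = 1)
  expect_equal(nrow(bench$records), 6L)
  expect_true(all(c("accuracy", "snr", "sns", "bin") %in% names(bench$records)))
  expect_true(all(bench$summary$n >= 1))
  expect_true(all(bench$summary$ci_lo <= bench$summary$mean_accuracy &
                    bench$summary$mean_accuracy <= bench$summary$ci_hi))
})

test_that("mean accuracy does not degrade as SNR grows on a small ladder", {
  accs <- vapply(c(0.05, 0.3), function(snr) {
    total <- round(1e4 * snr / 0.344)
    mean(vapply(1:6, function(i) {
      bio <- synth_biological_profile(total = total, seed = 100 * snr + i)
      smp <- add_ffpe_noise(bio, "unrepaired", 1e4, seed = 17 + i)
      fit <- ffpe_correct(smp$observed, "unrepaired",
                          control = correction_control(n_restarts = 5),
                          seed = 1)
      evaluate_correction(smp, fit)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_gt(accs[2], accs[1])
})
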