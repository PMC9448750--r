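test_that("generalized KL matches hand-evaluated cases", {
  expect_equal(generalized_kl(c(2, 1), c(1, 1)), 2 * log(2) - 1)
  expect_equal(generalized_kl(c(0, 3), c(5, 3)), 5)
  v <- rgamma(30, 2)
  expect_equal(generalized_kl(v, v), 0)
  expect_error(generalized_kl(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(generalized_kl(c(1, 2), c(0, 1)), "zero")
})

test_that("one multiplicative step reproduces the hand-worked update", {
  # V = [4, 0], identity basis columns, H = [1, 1]: H-update gives [4, 0]
  V <- c(4, 0)
  W <- diag(2)
  st <- multiplicative_step(V, W, c(1, 1))
  expect_equal(unname(st$H), c(4, 0), tolerance = 1e-9)
  # exact factorization is a fixed point
  W2 <- cbind(c(0.3, 0.7), c(0.6, 0.4))
  H2 <- c(10, 5)
  V2 <- as.numeric(W2 %*% H2)
  st2 <- multiplicative_step(V2, W2, H2)
  expect_equal(st2$H, H2, tolerance = 1e-8)
  expect_equal(st2$W, W2, tolerance = 1e-8)
})

test_that("each multiplicative step is non-increasing in generalized KL", {
  worst <- 0
  for (s in 1:200) {
    inst <- rand_nmf_instance(s)
    kl0 <- generalized_kl(inst$V, as.numeric(inst$W %*% inst$H) + 1e-12)
    st <- multiplicative_step(inst$V, inst$W, inst$H)
    kl1 <- generalized_kl(inst$V, as.numeric(st$W %*% st$H) + 1e-12)
    worst <- max(worst, (kl1 - kl0) / max(kl0, 1e-12))
  }
  expect_lte(worst, 1e-8)
})

test_that("restart traces are monotone and respect the iteration contract", {
  sig <- bundled_signatures("unrepaired")
  bio <- synth_biological_profile(total = 8000, seed = 2)
  smp <- add_ffpe_noise(bio, sig, 5000, seed = 3)
  sol <- run_restart(smp$observed$counts, sig$probabilities, seed = 7)
  expect_gte(sol$n_iter, 200)
  expect_lte(sol$n_iter, 3000)
  d <- diff(sol$kl_trace)
  expect_true(all(d <= 1e-8 * pmax(sol$kl_trace[-length(sol$kl_trace)], 1)))
  expect_error(run_restart(numeric(96), sig$probabilities), "empty")
})

test_that("pure artefact input is attributed to the artefact signature", {
  sig <- bundled_signatures("unrepaired")
  ctrl <- correction_control(n_restarts = 5)
  shares <- vapply(1:20, function(s) {
    v <- with_seed_test(s, as.numeric(rmultinom(1, 20000, sig$probabilities)))
    fit <- ffpe_correct(sbs_catalogue(v), sig, control = ctrl, seed = s)
    unname(fit$H["biological"] / sum(fit$H))
  }, numeric(1))
  expect_lt(mean(shares), 0.1)
  # shallower catalogues leave more sampling residual to the free spectrum,
  # but the artefact still dominates
  shares2k <- vapply(1:10, function(s) {
    v <- with_seed_test(s, as.numeric(rmultinom(1, 2000, sig$probabilities)))
    fit <- ffpe_correct(sbs_catalogue(v), sig, control = ctrl, seed = s)
    unname(fit$H["biological"] / sum(fit$H))
  }, numeric(1))
  expect_lt(mean(shares2k), 0.25)
  expect_gt(mean(shares2k), mean(shares))
})

test_that("a catalogue with no C>T mutations needs no correction", {
  sig <- bundled_signatures("unrepaired")  # all mass on C>T
  v <- numeric(96); v[1:16] <- 50          # C>A only
  fit <- ffpe_correct(sbs_catalogue(v), sig,
                      control = correction_control(n_restarts = 5), seed = 1)
  expect_lt(unname(fit$H["artefact"]), 1)
  expect_equal(unname(fit$corrected), v, tolerance = 1e-3)
})

test_that("correction is deterministic and conserves activity mass", {
  bio <- synth_biological_profile(total = 15000, seed = 4)
  smp <- add_ffpe_noise(bio, "unrepaired", 1e4, seed = 5)
  ctrl <- correction_control(n_restarts = 4)
  f1 <- ffpe_correct(smp$observed, "unrepaired", control = ctrl, seed = 9)
  f2 <- ffpe_correct(smp$observed, "unrepaired", control = ctrl, seed = 9)
  expect_identical(f1$W2, f2$W2)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$restarts, f2$restarts)
  # noise profile integrates to H1; corrected outputs are non-negative
  expect_equal(sum(f1$noise_profile), unname(f1$H["artefact"]),
               tolerance = 1e-6)
  expect_true(all(f1$corrected >= 0))
  expect_true(all(f1$noise_profile >= 0))
  # at convergence the reconstruction explains the observed catalogue
  expect_lt(mean(f1$restarts$kl_final) / sum(f1$observed), 0.05)
  # conservation: artefact + model mass equals the reconstruction mass
  expect_equal(sum(f1$noise_profile) + sum(f1$corrected_model),
               sum(fitted(f1)), tolerance = 1e-9)
})

test_that("generative recovery: corrected profile matches the hidden biology", {
  bio <- synth_biological_profile(total = 30000, seed = 2)
  smp <- add_ffpe_noise(bio, "unrepaired", 1e4, seed = 3)
  fit <- ffpe_correct(smp$observed, "unrepaired",
                      control = correction_control(n_restarts = 20), seed = 1)
  acc <- evaluate_correction(smp, fit)
  expect_gt(acc$accuracy, 0.9)
  expect_lt(smp$sns, 0.8)
  # 80c mode fits the reduced spectrum
  fit80 <- ffpe_correct(smp$observed, "unrepaired", channels = "80c",
                        control = correction_control(n_restarts = 5), seed = 1)
  expect_length(fit80$corrected, 80L)
  expect_gt(evaluate_correction(smp, fit80)$accuracy, 0.9)
})

test_that("restart variance widens when biology mimics the artefact signature", {
  sig <- bundled_signatures("unrepaired")
  mkbio <- function(ct_shape, seed) {
    p <- numeric(96)
    p[channel_mask("CT")] <- 0.5 * ct_shape / sum(ct_shape)
    p[1:16] <- 0.5 / 16
    with_seed_test(seed, as.numeric(rmultinom(1, 20000, p)))
  }
  ct_like <- sig$probabilities[channel_mask("CT")]
  ct_unlike <- numeric(16); ct_unlike[c(3, 7, 11, 15)] <- 1  # CpG spikes
  sds <- sapply(list(like = ct_like, unlike = ct_unlike), function(shape) {
    mean(sapply(1:3, function(s) {
      smp <- add_ffpe_noise(sbs_catalogue(mkbio(shape, s)), sig, 1e4,
                            seed = s + 50)
      fit <- ffpe_correct(smp$observed, sig,
                          control = correction_control(n_restarts = 20),
                          seed = 1)
      sd(fit$restarts$H1)
    }))
  })
  expect_gt(sds["like"], sds["unlike"])
})
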