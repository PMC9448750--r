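test_that("artefact signature invariants are enforced", {
  p <- numeric(96); p[channel_mask("CT")] <- 1 / 16
  expect_s3_class(ffpe_signature(p, "unrepaired"), "ffpe_signature")
  bad_tc <- p; bad_tc[channel_mask("TC")[1]] <- 0.01
  expect_error(ffpe_signature(bad_tc / sum(bad_tc), "unrepaired"), "T>C")
  expect_error(ffpe_signature(p * 2, "unrepaired"), "sum to 1")
  expect_error(ffpe_signature(c(p, 0), "unrepaired"), "96")
})

test_that("bundled signatures satisfy all invariants", {
  for (proto in c("unrepaired", "repaired")) {
    sig <- bundled_signatures(proto)
    expect_equal(sum(sig$probabilities), 1, tolerance = 1e-9)
    expect_true(all(sig$probabilities >= 0))
    expect_true(all(sig$probabilities[channel_mask("TC")] == 0))
    expect_equal(sig$protocol, proto)
  }
  # the repaired (UDG) signature concentrates C>T mass at CpG contexts,
  # the unrepaired one spreads it broadly
  rep_sig <- bundled_signatures("repaired")$probabilities
  unrep <- bundled_signatures("unrepaired")$probabilities
  cpg <- c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")
  expect_gt(sum(rep_sig[cpg]), 0.8)
  expect_lt(sum(unrep[cpg]), 0.3)
  expect_error(bundled_signatures("fresh"), "arg")
})

test_that("sample sets zero T>C and renormalize rows", {
  m <- matrix(runif(5 * 96), 5, 96)
  set <- sample_set(m, labels = c("unrepaired", "unrepaired", "repaired",
                                  "repaired", "repaired"))
  expect_equal(unname(rowSums(set$profiles)), rep(1, 5))
  expect_true(all(set$profiles[, channel_mask("TC")] == 0))
  expect_error(sample_set(m, labels = rep("ff", 5)), "label")
})

test_that("embedding is deterministic and separates distinct clusters", {
  set <- make_two_cluster_set(n_per = 8, conc = 800, seed = 11)
  e1 <- embed_profiles(set, seed = 3, n_iter = 300)
  e2 <- embed_profiles(set, seed = 3, n_iter = 300)
  expect_identical(e1$coords, e2$coords)
  # within-group embedded distances smaller than between-group
  d <- as.matrix(dist(e1$coords))
  same <- outer(set$labels, set$labels, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))
  # embedding params recorded for provenance
  expect_equal(e1$params$perplexity, min(30, floor((16 - 1) / 3)))
  tiny <- sample_set(set$profiles[1:3, ], labels = set$labels[1:3])
  expect_error(embed_profiles(tiny), "too few|>= 5")
})

test_that("density-based selection keeps the dense core", {
  # 3 coincident points plus a distant outlier: quota 2, both from the trio
  # (exactly tied densities break toward the lower original index)
  emb <- list(coords = rbind(c(0, 0), c(0, 0), c(0, 0), c(10, 10)))
  sel <- select_representatives(emb, labels = rep("unrepaired", 4))
  expect_equal(sel$unrepaired, c(1, 2))
  # near-coincident trio: both selections still come from the dense core
  emb_j <- list(coords = rbind(c(0, 0), c(0.01, 0), c(0, 0.01), c(10, 10)))
  sel_j <- select_representatives(emb_j, labels = rep("unrepaired", 4))
  expect_length(sel_j$unrepaired, 2L)
  expect_true(all(sel_j$unrepaired %in% 1:3))
  # brute-force KDE check: densities of the trio exceed the outlier's
  co <- emb$coords
  h <- apply(co, 2, sd) * 4^(-1 / 6)
  dens <- sapply(1:4, function(i)
    mean(exp(-((co[i, 1] - co[, 1])^2 / h[1]^2 +
               (co[i, 2] - co[, 2])^2 / h[2]^2) / 2)) / (2 * pi * h[1] * h[2]))
  expect_true(all(dens[1:3] > dens[4]))
  # all points coincident: degenerate, all kept with warning
  emb2 <- list(coords = matrix(1, 4, 2))
  expect_warning(sel2 <- select_representatives(emb2, rep("repaired", 4)),
                 "degenerate")
  expect_equal(sel2$repaired, 1:4)
  # fraction = 1 returns everything
  sel3 <- select_representatives(emb, rep("unrepaired", 4), fraction = 1)
  expect_equal(sel3$unrepaired, 1:4)
})

test_that("candidate signature is the renormalized mean of selected profiles", {
  set <- make_two_cluster_set(n_per = 4, seed = 5)
  expect_equal(candidate_signature(set, 2), unname(set$profiles[2, ]),
               ignore_attr = TRUE)
  two <- candidate_signature(set, c(1, 2))
  expect_equal(two, colMeans(set$profiles[1:2, ]) /
                 sum(colMeans(set$profiles[1:2, ])), ignore_attr = TRUE)
  # independent per-channel arithmetic mean
  idx <- c(1, 3, 4)
  manual <- sapply(seq_len(96), function(j) mean(set$profiles[idx, j]))
  expect_equal(unname(candidate_signature(set, idx)), manual / sum(manual))
  expect_error(candidate_signature(set, integer(0)), "empty")
})

test_that("signature derivation recovers a known generating target", {
  # identical profiles: derived signature equals that profile for any n_seeds
  p <- bundled_signatures("repaired")$probabilities
  m <- rbind(matrix(rep(p, 6), 6, byrow = TRUE),
             matrix(rep(bundled_signatures("unrepaired")$probabilities, 6),
                    6, byrow = TRUE))
  set_id <- sample_set(m, rep(c("repaired", "unrepaired"), each = 6))
  ds <- derive_noise_signature(set_id, "repaired", n_seeds = 2, n_iter = 120)
  expect_equal(unname(ds$probabilities), unname(p), tolerance = 1e-9)
  # Dirichlet-jittered cohort around the unrepaired target (concentration 500)
  set <- make_two_cluster_set(n_per = 16, conc = 500, seed = 42)
  target <- bundled_signatures("unrepaired")$probabilities
  ds2 <- derive_noise_signature(set, "unrepaired", n_seeds = 5, n_iter = 300)
  expect_gte(cosine_sim(ds2$probabilities, target), 0.99)
  expect_equal(ds2$provenance, "derived")
  expect_equal(ds2$seeds, 0:4)
  expect_error(derive_noise_signature(
    sample_set(m[1:6, ], rep("repaired", 6)), "unrepaired"), "protocol")
})

test_that("candidate averaging commutes with renormalization for unit-sum candidates", {
  set <- make_two_cluster_set(n_per = 5, seed = 9)
  idx_sets <- list(c(1, 2), c(2, 3), c(1, 4, 5))
  cands <- sapply(idx_sets, function(i) candidate_signature(set, i))
  avg <- rowMeans(cands)
  expect_equal(avg / sum(avg), avg, tolerance = 1e-12)
})
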