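#' Bundled synthetic reference signature set
#'
#' Loads the packaged reference signatures used by the simulator and the
#' examples. They are synthetic stand-ins shaped after well-known COSMIC
#' signature classes: `SBS1like` (clock-like CpG C>T spikes from
#' 5-methylcytosine deamination), `SBS5like` (flat across all 96 channels),
#' `SBS18like` (reactive-oxygen-species C>A) and `SBS40like` (flat with a
#' mild tilt, partially confusable with `SBS5like`).
#'
#' @return 96 x 4 probability matrix, columns summing to 1.
#' @export
reference_signatures <- function() {
  path <- system.file("extdata", "synthetic_reference_signatures.tsv",
                      package = "ffpecorrect", mustWork = TRUE)
  read_signature_tsv(path)
}

.default_activities <- c(SBS1like = 0.25, SBS5like = 0.55, SBS18like = 0.20)

#' Draw a synthetic biological mutation catalogue from a signature mixture
#'
#' A multinomial draw of `total` mutations from the mixture distribution
#' `signatures %*% activities`.
#'
#' @param signatures Channels x signatures probability matrix; default the
#'   bundled synthetic reference set.
#' @param activities Named relative activities summing to 1; default a
#'   colorectal-like mixture of clock-like, flat and ROS signatures.
#' @param total Number of mutations to draw (> 0).
#' @param seed RNG seed.
#' @param sample_id Catalogue id.
#' @return An [sbs_catalogue()] with the generating `activities`, `total`
#'   and mixture stored in `metadata`.
#' @export
synth_biological_profile <- function(signatures = NULL, activities = NULL,
                                     total, seed = 0L,
                                     sample_id = "synthetic") {
  if (is.null(signatures)) signatures <- reference_signatures()
  if (is.null(activities))
    activities <- .default_activities
  if (total <= 0) stop("total must be positive", call. = FALSE)
  activities <- activities[intersect(names(activities), colnames(signatures))]
  if (abs(sum(activities) - 1) > 1e-9)
    stop("activities must sum to 1", call. = FALSE)
  p <- as.numeric(signatures[, names(activities), drop = FALSE] %*% activities)
  counts <- with_seed(seed, as.numeric(stats::rmultinom(1, size = total, prob = p)))
  sbs_catalogue(counts, sample_id = sample_id,
                metadata = list(activities = activities, total = total,
                                mixture = stats::setNames(p, channel_labels())))
}

#' Signal-to-noise ratio of a biological catalogue
#'
#' Biological C>T count divided by the (expected) injected artefact count.
#'
#' @param bio Biological [sbs_catalogue()] or 96-vector.
#' @param noise_total Expected artefact count.
#' @return SNR, or `NA` when `noise_total` is 0.
#' @export
compute_snr <- function(bio, noise_total) {
  v <- if (inherits(bio, "sbs_catalogue")) bio$counts else as.numeric(bio)
  if (noise_total <= 0) return(NA_real_)
  sum(v[channel_mask("CT")]) / noise_total
}

#' Signal-to-noise similarity
#'
#' Cosine similarity on the 16 C>T channels between the biological
#' catalogue (the signal) and the FFPE artefact signature. A high SNS means
#' the artefact is confusable with the biology and correction is hard.
#'
#' @param bio Biological [sbs_catalogue()] or 96-vector.
#' @param W1 An [ffpe_signature()] or 96-vector of probabilities.
#' @return SNS in `[0, 1]`, or `NA` when the catalogue has no C>T counts.
#' @export
compute_sns <- function(bio, W1) {
  v <- if (inherits(bio, "sbs_catalogue")) bio$counts else as.numeric(bio)
  w <- if (inherits(W1, "ffpe_signature")) W1$probabilities else as.numeric(W1)
  ct <- channel_mask("CT")
  if (sum(v[ct]) == 0 || sum(w[ct]) == 0) return(NA_real_)
  cosine_sim(v, w, mask = ct)
}

#' Inject Poisson formalin artefacts into a biological catalogue
#'
#' Per-channel independent Poisson noise with mean `noise_total * W1_i`
#' (equivalently a Poisson(`noise_total`) total distributed multinomially
#' over the signature). By default the T>C channels of the observed
#' catalogue are zeroed afterwards, emulating the recommended removal of
#' batch-related T>C mutations of unknown origin.
#'
#' @param bio Biological truth [sbs_catalogue()].
#' @param W1 Artefact signature (an [ffpe_signature()], protocol name, or
#'   96-vector).
#' @param noise_total Expected artefact count (>= 0).
#' @param seed RNG seed.
#' @param drop_TC Zero the T>C channels of the observed catalogue.
#' @return Object of class `ffpe_synthetic_sample`: `bio`, `noise`,
#'   `observed` catalogues plus `snr`, `sns` and `protocol`.
#' @export
add_ffpe_noise <- function(bio, W1, noise_total, seed = 0L, drop_TC = TRUE) {
  if (is.character(W1)) W1 <- bundled_signatures(W1)
  w <- if (inherits(W1, "ffpe_signature")) W1$probabilities else as.numeric(W1)
  protocol <- if (inherits(W1, "ffpe_signature")) W1$protocol else "custom"
  if (noise_total < 0) stop("noise_total must be >= 0", call. = FALSE)
  noise <- with_seed(seed, stats::rpois(96L, lambda = noise_total * w))
  observed <- bio$counts + noise
  if (drop_TC) observed[channel_mask("TC")] <- 0
  structure(list(
    bio = bio,
    noise = sbs_catalogue(noise, paste0(bio$sample_id, ".noise")),
    observed = sbs_catalogue(observed, paste0(bio$sample_id, ".ffpe"),
                             metadata = list(drop_TC = drop_TC)),
    snr = compute_snr(bio, noise_total),
    sns = compute_sns(bio, w),
    noise_total = noise_total,
    protocol = protocol,
    drop_TC = drop_TC
  ), class = "ffpe_synthetic_sample")
}

#' @export
print.ffpe_synthetic_sample <- function(x, ...) {
  cat("Synthetic FFPE sample '", x$observed$sample_id, "' (", x$protocol,
      ")\n  bio ", format(total(x$bio)), " + noise ",
      format(sum(x$noise$counts)), " mutations; SNR ",
      format(round(x$snr, 3)), ", SNS ", format(round(x$sns, 3)),
      if (x$drop_TC) "; T>C dropped", "\n", sep = "")
  invisible(x)
}

#' Score a correction against the known biological truth
#'
#' Accuracy is the cosine similarity on the C>T channels between the
#' corrected catalogue and the biological truth; a sample is well corrected
#' when accuracy is strictly greater than `threshold`.
#'
#' @param sample An `ffpe_synthetic_sample`.
#' @param fit The corresponding [ffpe_correct()] fit.
#' @param threshold Well-corrected cutoff (default 0.90, strict).
#' @return List with `accuracy`, `well_corrected`, `snr`, `sns`, `protocol`.
#' @export
evaluate_correction <- function(sample, fit, threshold = 0.90) {
  bio <- sample$bio$counts
  corrected <- predict(fit, "corrected")
  if (fit$channels == "80c") bio <- reduce_to_80c(bio)
  ct_bio <- sum(sample$bio$counts[channel_mask("CT")])
  ct_corr <- if (fit$channels == "80c")
    sum(corrected[match(intersect(channel_mask("CT"), channel_mask("NON_TC")),
                        channel_mask("NON_TC"))])
  else sum(corrected[channel_mask("CT")])
  acc <- if (ct_bio == 0 || ct_corr == 0) NA_real_
         else cosine_sim(corrected, bio, mask = "CT")
  list(accuracy = acc,
       well_corrected = if (is.na(acc)) NA else acc > threshold,
       snr = sample$snr, sns = sample$sns, protocol = sample$protocol)
}

# Deterministic child-seed derivation: child i of master seed s is
# (s + 1000003 * i) mod (2^31 - 1), kept within 32-bit integer range.
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Simulate a cohort of FFPE samples
#'
#' Draws `n` biological catalogues from per-sample signature mixtures
#' (activities jittered around `activities` by a Dirichlet with
#' concentration `conc`, totals log-uniform over `total_range`) and injects
#' Poisson artefacts. One master seed derives per-sample child seeds
#' deterministically.
#'
#' @param n Number of samples.
#' @param noise_total Expected artefacts per sample (default `1e4`).
#' @param protocol Artefact protocol for the injected noise.
#' @param signatures,activities Mixture spec (defaults: bundled synthetic
#'   reference set; colorectal-like mixture).
#' @param total_range Biological totals drawn log-uniformly in this range.
#' @param conc Dirichlet concentration of the per-sample activity jitter.
#' @param seed Master seed.
#' @param drop_TC Zero T>C channels of observed catalogues.
#' @return List of `ffpe_synthetic_sample` objects; each biological
#'   catalogue's metadata records its true activities.
#' @export
simulate_cohort <- function(n, noise_total = 1e4,
                            protocol = c("unrepaired", "repaired"),
                            signatures = NULL, activities = NULL,
                            total_range = c(1e4, 1e5), conc = 10,
                            seed = 1L, drop_TC = TRUE) {
  protocol <- match.arg(protocol)
  if (is.null(signatures)) signatures <- reference_signatures()
  if (is.null(activities)) activities <- .default_activities
  W1 <- bundled_signatures(protocol)
  lapply(seq_len(n), function(i) {
    s <- child_seed(seed, i)
    pars <- with_seed(s, {
      g <- stats::rgamma(length(activities), shape = conc * activities)
      list(act = stats::setNames(g / sum(g), names(activities)),
           total = round(exp(stats::runif(1, log(total_range[1]),
                                          log(total_range[2])))))
    })
    bio <- synth_biological_profile(signatures, pars$act, pars$total,
                                    seed = child_seed(s, 1L),
                                    sample_id = sprintf("sim%03d", i))
    add_ffpe_noise(bio, W1, noise_total, seed = child_seed(s, 2L),
                   drop_TC = drop_TC)
  })
}

#' Correct and evaluate a synthetic cohort
#'
#' Runs [ffpe_correct()] on every sample's observed catalogue, scores the
#' corrections against the biological truth, and summarises mean accuracy
#' (with 95% confidence intervals) within biological C>T-load quantile bins
#' (0-10, 10-50, 50-90, 90-100 percentiles) and by protocol.
#'
#' @param samples List of `ffpe_synthetic_sample` (see [simulate_cohort()]).
#' @param signature Artefact signature used for correction; default the
#'   bundled signature matching each sample's protocol.
#' @param channels `"96c"` or `"80c"`.
#' @param control A [correction_control()].
#' @param seed Base seed passed to each correction.
#' @param threshold Well-corrected cutoff.
#' @return List with `records` (per-sample data frame: accuracy,
#'   well_corrected, snr, sns, bin, protocol) and `summary` (per bin x
#'   protocol: n, mean accuracy, 95% CI, fraction well corrected).
#' @export
benchmark_cohort <- function(samples, signature = NULL, channels = "96c",
                             control = correction_control(), seed = 1L,
                             threshold = 0.90) {
  stopifnot(length(samples) >= 1L)
  recs <- lapply(samples, function(smp) {
    sig <- signature %||% bundled_signatures(smp$protocol)
    fit <- ffpe_correct(smp$observed, sig, channels = channels,
                        control = control, seed = seed)
    ev <- evaluate_correction(smp, fit, threshold = threshold)
    data.frame(sample_id = smp$bio$sample_id,
               ct_load = sum(smp$bio$counts[channel_mask("CT")]),
               accuracy = ev$accuracy,
               well_corrected = ev$well_corrected,
               snr = ev$snr, sns = ev$sns, protocol = ev$protocol,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  qs <- stats::quantile(records$ct_load, c(0, 0.1, 0.5, 0.9, 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  records$bin <- cut(records$ct_load, breaks = unique(qs),
                     labels = c("Q0-10", "Q10-50", "Q50-90", "Q90-100")
                     [seq_len(length(unique(qs)) - 1)],
                     include.lowest = TRUE)
  grp <- interaction(records$bin, records$protocol, drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, grp), function(d) {
    ok <- !is.na(d$accuracy)
    m <- mean(d$accuracy[ok])
    se <- if (sum(ok) > 1) stats::sd(d$accuracy[ok]) / sqrt(sum(ok)) else 0
    data.frame(bin = d$bin[1], protocol = d$protocol[1], n = nrow(d),
               mean_accuracy = m, ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
               frac_well_corrected = mean(d$well_corrected[ok]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}
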