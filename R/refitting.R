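#' Refit activities of a fixed signature set to a catalogue
#'
#' Solves `V ~ S %*% h` for non-negative activities `h` with every signature
#' column fixed, by the same multiplicative KL updates and batched
#' convergence machinery as the artefact correction. With all columns fixed
#' the objective is convex in `h`, so a single deterministic run from an
#' equal-split initialisation suffices (no restarts).
#'
#' @param catalogue An [sbs_catalogue()], or a numeric count vector whose
#'   length matches `nrow(signatures)` (96 or 80 channels).
#' @param signatures Numeric matrix, channels x signatures, each column
#'   summing to 1 (see [read_signature_tsv()]); 80-row matrices pair with
#'   80-channel catalogues (see [reduce_to_80c()]).
#' @param control A [correction_control()] (`n_restarts` is ignored).
#' @return Object of class `sig_refit` with `absolute` and `relative`
#'   activities, the `reconstruction`, the final `kl` and iteration count.
#' @export
#' @examples
#' sigs <- reference_signatures()
#' v <- 700 * sigs[, 1] + 300 * sigs[, 2]
#' coef(refit_activities(v, sigs[, 1:2]), "relative")
refit_activities <- function(catalogue, signatures,
                             control = correction_control()) {
  V <- if (inherits(catalogue, "sbs_catalogue")) catalogue$counts
       else as.numeric(catalogue)
  S <- as.matrix(signatures)
  if (length(V) != nrow(S))
    stop("channel-mode mismatch: catalogue has ", length(V),
         " channels, signatures have ", nrow(S), call. = FALSE)
  if (sum(V) <= 0) stop("empty catalogue: nothing to refit", call. = FALSE)
  if (any(abs(colSums(S) - 1) > 1e-6))
    stop("signature columns must sum to 1", call. = FALSE)
  k <- ncol(S)
  eps <- control$epsilon
  h <- rep(sum(V) / k, k)
  kl <- numeric(control$max_iter)
  n_iter <- control$max_iter
  for (i in seq_len(control$max_iter)) {
    vhat <- as.numeric(S %*% h)
    ratio <- V / (vhat + eps)
    h <- h * as.numeric(crossprod(S, ratio))
    vhat <- as.numeric(S %*% h)
    kl[i] <- generalized_kl(V, vhat + eps)
    b <- control$batch
    if (i >= control$min_iter && i %% b == 0L) {
      recent <- mean(kl[(i - b + 1L):i])
      previous <- mean(kl[(i - 2L * b + 1L):(i - b)])
      if (previous == 0 || recent / previous >= control$conv_ratio) {
        n_iter <- i
        break
      }
    }
  }
  names(h) <- colnames(S)
  structure(list(
    absolute = h,
    relative = h / sum(h),
    reconstruction = stats::setNames(as.numeric(S %*% h), rownames(S)),
    kl = kl[n_iter],
    n_iter = n_iter,
    signatures = colnames(S),
    channels = if (nrow(S) == 96L) "96c" else "80c"
  ), class = "sig_refit")
}

#' @export
print.sig_refit <- function(x, ...) {
  cat("Signature refit (", x$channels, "), ", length(x$absolute),
      " signatures, ", x$n_iter, " iterations, final KL ",
      format(x$kl, digits = 4), "\n", sep = "")
  print(round(rbind(absolute = x$absolute, relative = x$relative), 3))
  invisible(x)
}

#' @export
coef.sig_refit <- function(object, type = c("absolute", "relative"), ...) {
  type <- match.arg(type)
  object[[type]]
}

#' @export
fitted.sig_refit <- function(object, ...) object$reconstruction

#' Binary presence calls from relative activities
#'
#' A signature is called present when its relative activity is strictly
#' greater than `threshold`; a relative contribution exactly at the
#' threshold counts as absent.
#'
#' @param rel Relative activities (sum to 1).
#' @param threshold Presence cutoff (default 0.1).
#' @return Named integer vector of 0/1 calls.
#' @export
presence_calls <- function(rel, threshold = 0.1) {
  stats::setNames(as.integer(rel > threshold), names(rel))
}

#' Score presence calls against truth
#'
#' @param calls,truth 0/1 vectors (same order).
#' @return List with confusion counts `TP`, `FP`, `FN`, `TN`, plus `recall`,
#'   `fdr` and `error_rate`.
#' @export
score_presence <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  calls <- as.integer(calls); truth <- as.integer(truth)
  tp <- sum(calls == 1 & truth == 1); fp <- sum(calls == 1 & truth == 0)
  fn <- sum(calls == 0 & truth == 1); tn <- sum(calls == 0 & truth == 0)
  list(TP = tp, FP = fp, FN = fn, TN = tn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
       error_rate = (fp + fn) / length(calls))
}

#' Absolute error of inferred relative activities
#'
#' @param true_rel,inferred_rel Relative activity vectors with identical
#'   signature names in identical order (names checked when present).
#' @return List with per-signature `epsilon` and its `mean`.
#' @export
activity_error <- function(true_rel, inferred_rel) {
  stopifnot(length(true_rel) == length(inferred_rel))
  if (!is.null(names(true_rel)) && !is.null(names(inferred_rel)) &&
      !identical(names(true_rel), names(inferred_rel)))
    stop("signature name mismatch between true and inferred activities",
         call. = FALSE)
  eps <- abs(true_rel - inferred_rel)
  list(epsilon = eps, mean = mean(eps))
}

#' Cosine accuracy of a refit reconstruction against a truth profile
#'
#' @param refit A `sig_refit` (or any numeric reconstruction vector).
#' @param truth Truth catalogue/vector on the same channel set.
#' @param mask Optional channel mask (name or indices), e.g. `"CT"`.
#' @return Cosine similarity.
#' @export
reconstruction_accuracy <- function(refit, truth, mask = NULL) {
  rec <- if (inherits(refit, "sig_refit")) refit$reconstruction
         else as.numeric(refit)
  tv <- if (inherits(truth, "sbs_catalogue")) truth$counts else as.numeric(truth)
  cosine_sim(rec, tv, mask = mask)
}

#' Rescale an 80-channel activity onto the 96-channel scale
#'
#' An activity fitted on the non-T>C spectrum counts only non-T>C
#' mutations; dividing by the non-T>C mass of the corresponding 96-channel
#' signature restores the full-spectrum activity scale.
#'
#' @param act80 Absolute activity from an 80c refit (scalar or vector).
#' @param sig96 The signature's 96-channel probability vector (sums to 1).
#' @return Rescaled activity.
#' @export
rescale_80c_activity <- function(act80, sig96) {
  if (any(act80 < 0)) stop("negative activity", call. = FALSE)
  if (length(sig96) != 96L || abs(sum(sig96) - 1) > 1e-6)
    stop("sig96 must be a 96-channel probability vector", call. = FALSE)
  mass <- sum(sig96[channel_mask("NON_TC")])
  if (mass <= 0) stop("signature has zero non-T>C mass", call. = FALSE)
  act80 / mass
}

#' Inconsistency rate between 80c and 96c activity fits
#'
#' `log10(activity_80c / activity_96c)`; a fit is `well_refitted` when the
#' rate lies in `[-0.30, 0.18]`, i.e. an actual activity ratio between 0.5
#' and 1.5. Pairs with a zero or negative activity on either side yield an
#' `NA` rate and are counted rather than coerced to infinity.
#'
#' @param act80_rescaled Rescaled 80c activities (see
#'   [rescale_80c_activity()]).
#' @param act96 Matching 96c activities.
#' @param band Well-refitted band endpoints.
#' @return List with `rate`, logical `well_refitted` and `n_undefined`.
#' @export
inconsistency_rate <- function(act80_rescaled, act96,
                               band = c(-0.30, 0.18)) {
  stopifnot(length(act80_rescaled) == length(act96))
  ok <- act80_rescaled > 0 & act96 > 0
  rate <- rep(NA_real_, length(act96))
  rate[ok] <- log10(act80_rescaled[ok] / act96[ok])
  well <- !is.na(rate) & rate >= band[1] & rate <= band[2]
  well[is.na(rate)] <- NA
  list(rate = rate, well_refitted = well, n_undefined = sum(!ok))
}
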