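#' Control parameters for the multiplicative-update solver
#'
#' @param min_iter Minimum iterations before convergence may be declared.
#' @param max_iter Iteration cap.
#' @param batch Batch length for the convergence ratio: the mean generalized
#'   KL of the last `batch` iterations divided by the mean of the previous
#'   `batch`.
#' @param conv_ratio Convergence threshold: since KL is non-increasing the
#'   ratio is <= 1, and a ratio at or above this value means the divergence
#'   has plateaued.
#' @param n_restarts Number of random restarts averaged into the solution.
#' @param epsilon Division guard in the update rules; never added to
#'   reported outputs.
#' @return A list of class `correction_control`.
#' @export
correction_control <- function(min_iter = 200L, max_iter = 3000L, batch = 20L,
                               conv_ratio = 0.95, n_restarts = 100L,
                               epsilon = 1e-12) {
  stopifnot(min_iter >= 2L * batch, conv_ratio > 0, conv_ratio <= 1,
            n_restarts >= 1L, max_iter >= min_iter, epsilon > 0)
  structure(list(min_iter = as.integer(min_iter), max_iter = as.integer(max_iter),
                 batch = as.integer(batch), conv_ratio = conv_ratio,
                 n_restarts = as.integer(n_restarts), epsilon = epsilon),
            class = "correction_control")
}

#' Generalized Kullback-Leibler divergence
#'
#' `D(v || vhat) = sum_i v_i log(v_i / vhat_i) - v_i + vhat_i`, with zero
#' entries of `v` contributing `vhat_i` (the `v log v` term vanishes).
#'
#' @param v Observed non-negative vector.
#' @param vhat Reconstruction, positive wherever `v` is positive.
#' @return Non-negative divergence.
#' @export
#' @examples
#' generalized_kl(c(2, 1), c(1, 1))  # 2 log 2 - 1
generalized_kl <- function(v, vhat) {
  if (any(v < 0) || any(vhat < 0))
    stop("generalized KL requires non-negative inputs", call. = FALSE)
  stopifnot(length(v) == length(vhat))
  pos <- v > 0
  if (any(vhat[pos] == 0))
    stop("reconstruction is zero where observation is positive", call. = FALSE)
  sum(vhat) - sum(v) + sum(v[pos] * log(v[pos] / vhat[pos]))
}

#' One multiplicative update for the partially fixed two-column model
#'
#' Performs a single KL-NMF iteration (Lee-Seung multiplicative rules) on
#' `V ~ W %*% H` where column 1 of `W` is the fixed artefact signature and
#' column 2 is the free biological spectrum: both activities are updated
#' from the current reconstruction, then the free column is updated and
#' renormalized to sum to 1 with the scale factor absorbed into its
#' activity.
#'
#' @param V Observed count vector.
#' @param W Basis matrix with 2 columns, each summing to 1; column 1 is
#'   never changed.
#' @param H Length-2 activity vector.
#' @param epsilon Division guard.
#' @return List with updated `W` and `H`.
#' @export
multiplicative_step <- function(V, W, H, epsilon = 1e-12) {
  vhat <- as.numeric(W %*% H)
  ratio <- V / (vhat + epsilon)
  H <- H * as.numeric(crossprod(W, ratio)) / colSums(W)
  vhat <- as.numeric(W %*% H)
  ratio <- V / (vhat + epsilon)
  w2 <- W[, 2] * ratio
  s <- sum(w2)
  if (s > 0) {
    W[, 2] <- w2 / s
    H[2] <- H[2] * s
  }
  list(W = W, H = H)
}

#' Run one random restart of the artefact decomposition
#'
#' Initializes the free spectrum from a symmetric Dirichlet(1) draw and the
#' activities at an equal split of the total count with uniform jitter, then
#' iterates [multiplicative_step()] until the batched convergence ratio
#' plateaus (or `max_iter`).
#'
#' @param V Numeric count vector (96 or 80 channels).
#' @param W1 Artefact signature probabilities, same length, summing to 1.
#' @param control A [correction_control()].
#' @param seed RNG seed of this restart.
#' @return List with `W2`, `H1`, `H2`, `kl_trace`, `n_iter`, `seed`.
#' @export
run_restart <- function(V, W1, control = correction_control(), seed = 0L) {
  tot <- sum(V)
  if (tot <= 0) stop("empty catalogue: nothing to decompose", call. = FALSE)
  stopifnot(length(V) == length(W1))
  eps <- control$epsilon
  init <- with_seed(seed, {
    w2 <- stats::rgamma(length(V), shape = 1, rate = 1)
    list(W2 = w2 / sum(w2), H = tot / 2 * stats::runif(2, 0.5, 1.5))
  })
  W2 <- init$W2
  H <- init$H
  kl <- numeric(control$max_iter)
  n_iter <- control$max_iter
  for (i in seq_len(control$max_iter)) {
    vhat <- W1 * H[1] + W2 * H[2]
    ratio <- V / (vhat + eps)
    H[1] <- H[1] * sum(W1 * ratio)
    H[2] <- H[2] * sum(W2 * ratio)
    vhat <- W1 * H[1] + W2 * H[2]
    ratio <- V / (vhat + eps)
    w2 <- W2 * ratio
    s <- sum(w2)
    if (s > 0) {
      W2 <- w2 / s
      H[2] <- H[2] * s
    }
    vhat <- W1 * H[1] + W2 * H[2]
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
  list(W2 = W2, H1 = H[1], H2 = H[2], kl_trace = kl[seq_len(n_iter)],
       n_iter = n_iter, seed = seed)
}

#' Correct an FFPE mutational catalogue for formalin artefacts
#'
#' Decomposes an observed 96-channel (or 80-channel, non-T>C) catalogue `V`
#' into a fixed formalin artefact signature `W1` with activity `H1` and a
#' free biological spectrum `W2` with activity `H2`,
#' `V ~ W1 H1 + W2 H2`, by multiplicative-update minimisation of the
#' generalized Kullback-Leibler divergence. `n_restarts` random restarts are
#' run from different initialisations and their solutions averaged. The
#' primary corrected catalogue is the channel-wise subtraction
#' `max(V - H1 W1, 0)`; the smooth model-based alternative `H2 W2` is also
#' returned.
#'
#' @param catalogue An [sbs_catalogue()], or a numeric 96-vector of counts.
#' @param signature The artefact signature: `"unrepaired"` or `"repaired"`
#'   (bundled), an [ffpe_signature()], or a numeric 96-vector of
#'   probabilities.
#' @param channels `"96c"` (default) or `"80c"`; in 80c mode the T>C
#'   channels are dropped from both catalogue and signature (the signature
#'   is renormalized) before fitting.
#' @param control A [correction_control()].
#' @param seed Base seed; restart `r` uses `seed + r - 1`.
#' @return An object of class `ffpe_fit` with components `corrected`
#'   (subtraction-based corrected catalogue), `corrected_model`,
#'   `noise_profile` (`H1 W1`), `W2`, `H` (`c(artefact, biological)`),
#'   per-restart summaries and KL traces.
#' @seealso [refit_activities()] for downstream signature attribution.
#' @export
#' @examples
#' sig <- bundled_signatures("unrepaired")
#' bio <- synth_biological_profile(total = 5000, seed = 1)
#' smp <- add_ffpe_noise(bio, sig, noise_total = 2000, seed = 1)
#' fit <- ffpe_correct(smp$observed, sig,
#'                     control = correction_control(n_restarts = 2))
#' fit
ffpe_correct <- function(catalogue, signature = "unrepaired",
                         channels = c("96c", "80c"),
                         control = correction_control(), seed = 1L) {
  channels <- match.arg(channels)
  cl <- match.call()
  if (is.character(signature)) signature <- bundled_signatures(signature)
  w1_full <- if (inherits(signature, "ffpe_signature"))
    signature$probabilities else as.numeric(signature)
  if (length(w1_full) != 96L || abs(sum(w1_full) - 1) > 1e-6)
    stop("artefact signature must be a 96-channel probability vector",
         call. = FALSE)
  cat_obj <- if (inherits(catalogue, "sbs_catalogue")) catalogue
             else sbs_catalogue(catalogue)
  if (channels == "80c") {
    V <- reduce_to_80c(cat_obj)
    W1 <- reduce_to_80c(w1_full, renormalize = TRUE)
  } else {
    V <- cat_obj$counts
    W1 <- w1_full
  }
  if (sum(V) <= 0) stop("empty catalogue: nothing to decompose", call. = FALSE)
  seeds <- seed + seq_len(control$n_restarts) - 1L
  sols <- lapply(seeds, function(s) run_restart(V, W1, control, seed = s))
  W2 <- rowMeans(vapply(sols, `[[`, numeric(length(V)), "W2"))
  H1 <- mean(vapply(sols, `[[`, numeric(1), "H1"))
  H2 <- mean(vapply(sols, `[[`, numeric(1), "H2"))
  noise <- H1 * W1
  structure(list(
    sample_id = cat_obj$sample_id,
    channels = channels,
    observed = V,
    W1 = W1,
    W2 = stats::setNames(W2, names(V)),
    H = c(artefact = H1, biological = H2),
    noise_profile = stats::setNames(noise, names(V)),
    corrected = stats::setNames(pmax(V - noise, 0), names(V)),
    corrected_model = stats::setNames(H2 * W2, names(V)),
    restarts = data.frame(
      seed = seeds,
      H1 = vapply(sols, `[[`, numeric(1), "H1"),
      H2 = vapply(sols, `[[`, numeric(1), "H2"),
      n_iter = vapply(sols, `[[`, numeric(1), "n_iter"),
      kl_final = vapply(sols, function(s) utils::tail(s$kl_trace, 1), numeric(1))
    ),
    kl_traces = lapply(sols, `[[`, "kl_trace"),
    control = control,
    seed = seed,
    call = cl
  ), class = "ffpe_fit")
}

#' @export
print.ffpe_fit <- function(x, ...) {
  tot <- sum(x$observed)
  cat("FFPE artefact correction (", x$channels, ") for '", x$sample_id, "'\n",
      sep = "")
  cat(sprintf("  observed mutations: %.0f\n", tot))
  cat(sprintf("  artefact activity H1: %.1f (%.1f%% of total)\n",
              x$H["artefact"], 100 * x$H["artefact"] / tot))
  cat(sprintf("  biological activity H2: %.1f\n", x$H["biological"]))
  cat(sprintf("  restarts: %d; iterations %d-%d\n",
              nrow(x$restarts), min(x$restarts$n_iter), max(x$restarts$n_iter)))
  invisible(x)
}

#' @export
summary.ffpe_fit <- function(object, ...) {
  x <- object
  out <- list(
    sample_id = x$sample_id, channels = x$channels,
    total = sum(x$observed), H = x$H,
    H1_sd = stats::sd(x$restarts$H1),
    kl_final = mean(x$restarts$kl_final),
    kl_per_mutation = mean(x$restarts$kl_final) / sum(x$observed),
    corrected_total = sum(x$corrected)
  )
  class(out) <- "summary.ffpe_fit"
  out
}

#' @export
print.summary.ffpe_fit <- function(x, ...) {
  cat("FFPE correction summary ('", x$sample_id, "', ", x$channels, ")\n",
      sep = "")
  cat(sprintf("  total %.0f -> corrected %.0f mutations\n",
              x$total, x$corrected_total))
  cat(sprintf("  H1 = %.1f (restart sd %.2f), H2 = %.1f\n",
              x$H["artefact"], x$H1_sd, x$H["biological"]))
  cat(sprintf("  mean final KL %.3f (%.4f per mutation)\n",
              x$kl_final, x$kl_per_mutation))
  invisible(x)
}

#' @export
coef.ffpe_fit <- function(object, type = c("absolute", "relative"), ...) {
  type <- match.arg(type)
  h <- object$H
  if (type == "relative") h <- h / sum(h)
  h
}

#' @export
fitted.ffpe_fit <- function(object, ...) {
  object$W1 * object$H["artefact"] + object$W2 * object$H["biological"]
}

#' @export
residuals.ffpe_fit <- function(object, ...) {
  object$observed - fitted(object)
}

#' Extract profiles from a correction fit
#'
#' @param object An `ffpe_fit`.
#' @param type `"corrected"` (subtraction-based, default), `"model"`
#'   (`H2 W2`), `"noise"` (`H1 W1`) or `"reconstruction"` (`W H`).
#' @param ... Unused.
#' @return Named numeric vector on the fit's channel set.
#' @export
predict.ffpe_fit <- function(object, type = c("corrected", "model", "noise",
                                              "reconstruction"), ...) {
  type <- match.arg(type)
  switch(type,
    corrected = object$corrected,
    model = object$corrected_model,
    noise = object$noise_profile,
    reconstruction = fitted(object)
  )
}

#' Simulate observed catalogues from a correction fit
#'
#' Draws independent Poisson counts around the fitted reconstruction,
#' mirroring the noise model used by the package's simulator.
#'
#' @param object An `ffpe_fit`.
#' @param nsim Number of simulated catalogues.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A list of count vectors on the fit's channel set.
#' @export
simulate.ffpe_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  draw <- function() stats::setNames(stats::rpois(length(mu), mu), names(mu))
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}

#' @export
plot.ffpe_fit <- function(x, which = c("profiles", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$kl_traces[[1]]
    graphics::plot(seq_along(tr), tr, type = "l", log = "y",
                   xlab = "iteration", ylab = "generalized KL",
                   main = "Convergence (first restart)")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- c("C>A" = "#03BCEE", "C>G" = "black", "C>T" = "#E32926",
            "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")
  subs <- if (x$channels == "80c")
    sbs_channels()$substitution[channel_mask("NON_TC")]
  else sbs_channels()$substitution
  barcol <- cols[subs]
  graphics::barplot(x$observed, col = barcol, border = NA, names.arg = FALSE,
                    main = "observed", ylab = "count")
  graphics::barplot(x$noise_profile, col = barcol, border = NA,
                    names.arg = FALSE, main = "inferred artefact (H1 W1)",
                    ylab = "count")
  graphics::barplot(x$corrected, col = barcol, border = NA, names.arg = FALSE,
                    main = "corrected", ylab = "count")
  invisible(x)
}
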