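# Evaluate an expression under a given RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct an FFPE artefact signature
#'
#' A 96-channel probability vector with zero mass on the 16 T>C channels
#' (T>C mutations are batch-related, not formalin-induced, and are treated
#' as missing data).
#'
#' @param probabilities Numeric 96-vector, non-negative, summing to 1.
#' @param protocol `"unrepaired"` (no uracil-DNA-glycosylase treatment) or
#'   `"repaired"` (UDG-treated; only 5mC-derived CpG artefacts remain).
#' @param provenance `"fixture"` or `"derived"`.
#' @param seeds Optional integer vector of embedding seeds used to derive it.
#' @return An object of class `ffpe_signature`.
#' @export
ffpe_signature <- function(probabilities,
                           protocol = c("unrepaired", "repaired"),
                           provenance = c("derived", "fixture"),
                           seeds = NULL) {
  protocol <- match.arg(protocol)
  provenance <- match.arg(provenance)
  p <- as.numeric(probabilities)
  if (length(p) != 96L) stop("signature must have 96 channels", call. = FALSE)
  if (any(p < 0)) stop("signature entries must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("signature must sum to 1", call. = FALSE)
  if (any(p[channel_mask("TC")] != 0))
    stop("FFPE signatures carry zero mass on T>C channels", call. = FALSE)
  structure(
    list(probabilities = stats::setNames(p, channel_labels()),
         protocol = protocol, provenance = provenance, seeds = seeds),
    class = "ffpe_signature"
  )
}

#' @export
print.ffpe_signature <- function(x, ...) {
  ct <- sum(x$probabilities[channel_mask("CT")])
  cat("FFPE artefact signature (", x$protocol, ", ", x$provenance, ")\n",
      "  C>T mass: ", round(ct, 3), "; top channel: ",
      names(which.max(x$probabilities)), "\n", sep = "")
  invisible(x)
}

#' Bundled FFPE artefact signatures
#'
#' Loads the packaged artefact signatures. These are synthetic stand-ins
#' constructed to emulate the published formalin artefact spectra: the
#' unrepaired signature spreads C>T mass broadly across trinucleotide
#' contexts (cytosine deamination at any C), while the repaired signature
#' concentrates C>T mass at NCG (CpG) contexts, the residue of
#' 5-methylcytosine deamination that UDG treatment cannot excise. See the
#' package vignette for the construction recipe.
#'
#' @param protocol `"unrepaired"` or `"repaired"`.
#' @return An [ffpe_signature()] with provenance `"fixture"`.
#' @export
#' @examples
#' bundled_signatures("repaired")
bundled_signatures <- function(protocol = c("unrepaired", "repaired")) {
  protocol <- match.arg(protocol)
  path <- system.file("extdata", "synthetic_ffpe_signatures.tsv",
                      package = "ffpecorrect", mustWork = TRUE)
  mat <- read_signature_tsv(path)
  ffpe_signature(mat[, protocol], protocol = protocol, provenance = "fixture")
}

#' Assemble a labelled cohort of 80-channel-equivalent profiles
#'
#' Catalogues are converted to probability profiles with T>C channels forced
#' to zero before renormalization (T>C treated as missing data).
#'
#' @param catalogues List of [sbs_catalogue()] (or a numeric N x 96 matrix of
#'   counts/probabilities).
#' @param labels Character vector, one of `"unrepaired"`/`"repaired"` per
#'   sample.
#' @param study Optional per-sample study tag.
#' @return An object of class `ffpe_sample_set` with a `profiles` matrix
#'   (rows sum to 1, T>C entries exactly 0), `labels` and `study`.
#' @export
sample_set <- function(catalogues, labels, study = NULL) {
  if (is.matrix(catalogues)) {
    mat <- catalogues
  } else {
    mat <- do.call(rbind, lapply(catalogues, function(ct)
      if (inherits(ct, "sbs_catalogue")) ct$counts else as.numeric(ct)))
  }
  if (ncol(mat) != 96L) stop("profiles must have 96 channels", call. = FALSE)
  if (length(labels) != nrow(mat))
    stop("one label per sample required", call. = FALSE)
  if (!all(labels %in% c("unrepaired", "repaired")))
    stop("labels must be 'unrepaired' or 'repaired'", call. = FALSE)
  mat[, channel_mask("TC")] <- 0
  rs <- rowSums(mat)
  if (any(rs == 0)) stop("sample(s) with zero non-T>C mass", call. = FALSE)
  mat <- mat / rs
  colnames(mat) <- channel_labels()
  structure(list(profiles = mat, labels = labels,
                 study = study %||% rep("study", nrow(mat))),
            class = "ffpe_sample_set")
}

#' Two-dimensional stochastic embedding of a profile cohort
#'
#' Runs exact t-SNE on the precomputed pairwise cosine-distance matrix of
#' the cohort's non-T>C (80-channel) probabilities. Deterministic for a
#' fixed seed.
#'
#' @param set An [sample_set()].
#' @param seed Integer RNG seed for the embedding initialisation.
#' @param perplexity t-SNE perplexity; default `min(30, floor((N - 1) / 3))`.
#' @param n_iter Gradient-descent iterations.
#' @return List with `coords` (N x 2), `seed` and `params`.
#' @export
embed_profiles <- function(set, seed = 0L, perplexity = NULL, n_iter = 500L) {
  mat <- set$profiles
  n <- nrow(mat)
  if (n < 5L) stop("too few samples for embedding (need >= 5)", call. = FALSE)
  keep <- channel_mask("NON_TC")
  d <- 1 - .cosine_matrix(mat[, keep, drop = FALSE])
  perplexity <- perplexity %||% min(30L, floor((n - 1) / 3))
  coords <- with_seed(seed, Rtsne::Rtsne(
    stats::as.dist(d), perplexity = perplexity, theta = 0,
    max_iter = n_iter, is_distance = TRUE, pca = FALSE, verbose = FALSE
  )$Y)
  list(coords = coords, seed = seed,
       params = list(perplexity = perplexity, n_iter = n_iter,
                     distance = "cosine/80c", method = "exact t-SNE"))
}

.cosine_matrix <- function(mat) {
  norms <- sqrt(rowSums(mat^2))
  sim <- (mat %*% t(mat)) / outer(norms, norms)
  pmin(pmax(sim, -1), 1)
}

# Gaussian product-kernel density of 2-D points evaluated at the points
# themselves; Scott's rule bandwidth per coordinate. Returns NULL when the
# point cloud is degenerate (zero spread).
.kde2d_at_points <- function(coords) {
  n <- nrow(coords)
  h <- apply(coords, 2, stats::sd) * n^(-1 / 6)
  if (any(!is.finite(h)) || any(h == 0)) return(NULL)
  dx <- outer(coords[, 1], coords[, 1], "-") / h[1]
  dy <- outer(coords[, 2], coords[, 2], "-") / h[2]
  rowMeans(exp(-(dx^2 + dy^2) / 2)) / (2 * pi * h[1] * h[2])
}

#' Select high-density representative samples within each protocol group
#'
#' Within each label group a Gaussian kernel density estimate (Scott's rule)
#' is evaluated at every embedded point and the densest `fraction` of
#' samples is retained: points strictly above the group median density,
#' with median ties broken toward the lower original index until the quota
#' `ceiling(fraction * N)` is met. Outliers at the embedding fringe are
#' thereby excluded from signature averaging.
#'
#' @param emb An embedding from [embed_profiles()].
#' @param labels Per-sample protocol labels.
#' @param fraction Fraction of each group to keep (default top 50%).
#' @return Named list of integer index vectors, one per label present.
#' @export
select_representatives <- function(emb, labels, fraction = 0.5) {
  coords <- emb$coords
  out <- lapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) < 2L)
      stop("need at least 2 samples per label group", call. = FALSE)
    dens <- .kde2d_at_points(coords[idx, , drop = FALSE])
    if (is.null(dens)) {
      warning("degenerate group (coincident points): keeping all samples",
              call. = FALSE)
      return(idx)
    }
    quota <- ceiling(fraction * length(idx))
    ord <- order(-dens, seq_along(idx))
    sort(idx[ord[seq_len(quota)]])
  })
  out
}

#' Candidate artefact signature from a representative subset
#'
#' @param set An [sample_set()].
#' @param indices Row indices of the representative samples.
#' @return Named 96-vector: the per-channel mean of the selected profiles,
#'   renormalized to sum to 1 (T>C entries remain 0).
#' @export
candidate_signature <- function(set, indices) {
  if (length(indices) == 0L) stop("empty representative set", call. = FALSE)
  m <- colMeans(set$profiles[indices, , drop = FALSE])
  m / sum(m)
}

#' Derive an FFPE artefact signature from a labelled cohort
#'
#' Repeats embed -> density-based selection -> candidate averaging across
#' `n_seeds` embedding seeds (0 .. n_seeds - 1) and returns the per-channel
#' mean of all candidate signatures, renormalized.
#'
#' @param set An [sample_set()].
#' @param protocol Which label group to derive the signature for.
#' @param n_seeds Number of stochastic embedding repeats (default 100).
#' @param fraction Representative fraction per repeat.
#' @param n_iter t-SNE iterations per repeat.
#' @return An [ffpe_signature()] with provenance `"derived"`.
#' @export
derive_noise_signature <- function(set, protocol = c("unrepaired", "repaired"),
                                   n_seeds = 100L, fraction = 0.5,
                                   n_iter = 500L) {
  protocol <- match.arg(protocol)
  if (!protocol %in% set$labels)
    stop("no samples with protocol '", protocol, "' in the cohort", call. = FALSE)
  seeds <- seq_len(n_seeds) - 1L
  cands <- vapply(seeds, function(s) {
    emb <- embed_profiles(set, seed = s, n_iter = n_iter)
    sel <- select_representatives(emb, set$labels, fraction = fraction)
    candidate_signature(set, sel[[protocol]])
  }, numeric(96))
  final <- rowMeans(cands)
  ffpe_signature(final / sum(final), protocol = protocol,
                 provenance = "derived", seeds = seeds)
}
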