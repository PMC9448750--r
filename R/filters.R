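.mut_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

.sub_class <- function(df) {
  pur <- df$ref %in% c("A", "G")
  ref <- ifelse(pur, COMPLEMENT[df$ref], df$ref)
  alt <- ifelse(pur, COMPLEMENT[df$alt], df$alt)
  paste0(ref, ">", alt)
}

#' Concordance classification of mutations across samples
#'
#' A mutation (keyed by chrom, pos, ref, alt) is concordant when it is
#' observed in two or more distinct samples. Recurrent positions across
#' samples betray germline leakage or systematic pipeline artefacts, whereas
#' genuine formalin lesions hit near-random genomic positions.
#'
#' @param tables Either one data frame with a `sample_id` column or a named
#'   list of per-sample data frames, each with `chrom`, `pos`, `ref`, `alt`.
#' @return A list with `mutations` (the deduplicated per-sample table plus a
#'   logical `concordant` flag and a `substitution` class), `by_substitution`
#'   (concordant fraction of mutation instances per pyrimidine substitution
#'   class) and `pairwise` (per sample pair, the mean of the two directed
#'   shared fractions).
#' @export
concordance_classify <- function(tables) {
  if (is.data.frame(tables)) {
    df <- tables
  } else {
    df <- do.call(rbind, lapply(names(tables), function(s) {
      t <- tables[[s]]; t$sample_id <- s; t
    }))
  }
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt") %in% names(df)))
  key <- paste(df$sample_id, .mut_key(df))
  if (anyDuplicated(key)) {
    warning("duplicate mutation keys within a sample were deduplicated",
            call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  mk <- .mut_key(df)
  n_samples <- tapply(df$sample_id, mk, function(s) length(unique(s)))
  df$concordant <- as.vector(n_samples[mk] >= 2L)
  df$substitution <- .sub_class(df)
  by_sub <- tapply(df$concordant, df$substitution, mean)
  samples <- unique(df$sample_id)
  pairs <- if (length(samples) >= 2L) utils::combn(samples, 2L) else
    matrix(character(0), nrow = 2)
  pairwise <- data.frame(
    sample_a = pairs[1, ], sample_b = pairs[2, ],
    concordance = apply(pairs, 2, function(p) {
      ka <- mk[df$sample_id == p[1]]; kb <- mk[df$sample_id == p[2]]
      shared <- length(intersect(ka, kb))
      mean(c(shared / length(ka), shared / length(kb)))
    }),
    stringsAsFactors = FALSE
  )
  list(mutations = df,
       by_substitution = by_sub,
       pairwise = pairwise)
}

#' Filter a mutation list down to candidate FFPE-only artefacts
#'
#' Removes mutations that plausibly are genuine somatic or germline variants:
#' (1) detected in every fresh-frozen (FF) sample, (2) detected in the
#' matched normal, (3) carrying a posterior probability of being somatic
#' strictly above 0.90, (4) present in a supplied germline-site list.
#' Input order is preserved.
#'
#' @param ffpe_muts Data frame of FFPE-sample mutations (`chrom,pos,ref,alt`).
#' @param ff_muts Named list of per-FF-sample data frames (or one data frame
#'   with `sample_id`); a mutation is removed only when present in all of them.
#' @param normal_muts Data frame of matched-normal calls, or `NULL`.
#' @param germline_sites Data frame of known germline sites, or `NULL`.
#' @param somatic_posterior Optional named numeric: posterior probability per
#'   mutation key `"chrom:pos:ref:alt"`. If missing, criterion (3) is skipped
#'   with a warning.
#' @param posterior_cutoff Strict cutoff; mutations with posterior
#'   `> posterior_cutoff` are removed.
#' @return The filtered data frame.
#' @export
ffpe_only_filter <- function(ffpe_muts, ff_muts = NULL, normal_muts = NULL,
                             germline_sites = NULL, somatic_posterior = NULL,
                             posterior_cutoff = 0.90) {
  keys <- .mut_key(ffpe_muts)
  drop <- rep(FALSE, length(keys))
  if (!is.null(ff_muts) && length(ff_muts)) {
    if (is.data.frame(ff_muts)) {
      ff_keysets <- lapply(split(ff_muts, ff_muts$sample_id), .mut_key)
    } else ff_keysets <- lapply(ff_muts, .mut_key)
    in_all_ff <- Reduce(intersect, ff_keysets)
    drop <- drop | keys %in% in_all_ff
  }
  if (!is.null(normal_muts) && NROW(normal_muts))
    drop <- drop | keys %in% .mut_key(normal_muts)
  if (is.null(somatic_posterior)) {
    warning("no somatic posterior supplied: posterior filter skipped",
            call. = FALSE)
  } else {
    post <- somatic_posterior[keys]
    drop <- drop | (!is.na(post) & post > posterior_cutoff)
  }
  if (!is.null(germline_sites) && NROW(germline_sites))
    drop <- drop | keys %in% .mut_key(germline_sites)
  ffpe_muts[!drop, , drop = FALSE]
}

#' Concordant mutations between two WGS FFPE samples
#'
#' Variants present in both samples with at least `min_reads` supporting
#' reads in each are classified as concordant; in a tumour without a paired
#' fresh-frozen sample these approximate the true somatic mutation profile.
#'
#' @param mut_a,mut_b Data frames with `chrom,pos,ref,alt,supporting_reads`.
#' @param min_reads Minimum supporting reads required in both samples.
#' @return The concordant subset of `mut_a` (keys also present in `mut_b`).
#' @export
concordant_wgs <- function(mut_a, mut_b, min_reads = 5L) {
  stopifnot("supporting_reads" %in% names(mut_a),
            "supporting_reads" %in% names(mut_b))
  ka <- .mut_key(mut_a); kb <- .mut_key(mut_b)
  pass_b <- kb[mut_b$supporting_reads >= min_reads]
  keep <- mut_a$supporting_reads >= min_reads & ka %in% pass_b
  mut_a[keep, , drop = FALSE]
}
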