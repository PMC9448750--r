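#' Construct an SBS catalogue
#'
#' A catalogue is a named 96-vector of non-negative per-channel mutation
#' counts for one sample, in canonical channel order.
#'
#' @param counts Numeric vector of length 96 (or a named vector whose names
#'   are canonical channel labels, re-ordered automatically).
#' @param sample_id Sample identifier.
#' @param metadata Optional named list (study, protocol, ...).
#' @return An object of class `sbs_catalogue`.
#' @export
sbs_catalogue <- function(counts, sample_id = "sample", metadata = list()) {
  if (!is.null(names(counts)) && all(channel_labels() %in% names(counts)))
    counts <- counts[channel_labels()]
  counts <- as.numeric(counts)
  if (length(counts) != 96L)
    stop("a catalogue has exactly 96 channels, got ", length(counts), call. = FALSE)
  if (any(counts < 0) || anyNA(counts))
    stop("catalogue counts must be non-negative and non-missing", call. = FALSE)
  structure(
    list(counts = stats::setNames(counts, channel_labels()),
         sample_id = sample_id, metadata = metadata),
    class = "sbs_catalogue"
  )
}

#' @export
print.sbs_catalogue <- function(x, ...) {
  tot <- sum(x$counts)
  by_sub <- tapply(x$counts, sbs_channels()$substitution, sum)[SUBSTITUTIONS]
  cat("SBS catalogue '", x$sample_id, "': ", format(tot), " mutations\n", sep = "")
  print(round(by_sub, 1))
  invisible(x)
}

#' @export
total.sbs_catalogue <- function(x, ...) sum(x$counts)

#' Total mutation count
#' @param x An object with a count vector.
#' @param ... Unused.
#' @export
total <- function(x, ...) UseMethod("total")

#' Classify a single-nucleotide variant into its SBS channel
#'
#' Variants with a purine reference are reverse-complemented onto the
#' pyrimidine strand before channel assignment.
#'
#' @param ref,alt Single reference/alternate bases (forward strand, as in VCF).
#' @param context Reference trinucleotide centred on the variant position
#'   (forward strand), or a lookup `function(chrom, pos)` returning it when
#'   `chrom`/`pos` are supplied.
#' @param chrom,pos Optional coordinates passed to a `context` function.
#' @return One-row channel data frame (see [sbs_channels()]).
#' @export
#' @examples
#' classify_variant("G", "A", "TGT")$label  # folded to "A[C>T]A"
classify_variant <- function(ref, alt, context, chrom = NULL, pos = NULL) {
  if (is.function(context)) context <- context(chrom, pos)
  if (!ref %in% BASES || !alt %in% BASES || nchar(ref) != 1L || nchar(alt) != 1L)
    stop("unsupported variant: ref/alt must be single bases (no indel/MNV)",
         call. = FALSE)
  if (ref == alt) stop("ref and alt are identical", call. = FALSE)
  if (nchar(context) != 3L || !grepl("^[ACGT]{3}$", context))
    stop("context must be a 3-base ACGT string", call. = FALSE)
  if (substr(context, 2, 2) != ref)
    stop("reference mismatch: context centre '", substr(context, 2, 2),
         "' disagrees with ref '", ref, "'", call. = FALSE)
  if (ref %in% c("A", "G")) {  # fold onto pyrimidine strand
    ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
    context <- revcomp(context)
  }
  label <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                  substr(context, 3, 3))
  parse_channel(label)
}

#' Build a catalogue from classified mutation records
#'
#' @param records Data frame with at least a `channel` column of canonical
#'   labels (as from `classify_variant()$label`); an optional `sample_id`
#'   column must be constant.
#' @param sample_id Identifier; defaults to the records' shared sample_id.
#' @return An [sbs_catalogue()]. An empty record set yields a zero catalogue
#'   with a warning.
#' @export
build_catalogue <- function(records, sample_id = NULL) {
  if (NROW(records) == 0L) {
    warning("no mutation records: returning an all-zero catalogue", call. = FALSE)
    return(sbs_catalogue(numeric(96), sample_id %||% "sample",
                         metadata = list(empty = TRUE)))
  }
  if (!is.null(records$sample_id)) {
    ids <- unique(records$sample_id)
    if (length(ids) > 1L)
      stop("records span multiple samples: ", paste(ids, collapse = ", "),
           call. = FALSE)
    sample_id <- sample_id %||% ids
  }
  bad <- setdiff(unique(records$channel), channel_labels())
  if (length(bad))
    stop("unknown channel label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- table(factor(records$channel, levels = channel_labels()))
  sbs_catalogue(as.numeric(counts), sample_id %||% "sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a panel catalogue onto genome trinucleotide context
#'
#' Counts observed on a targeted panel are re-weighted channel-wise by the
#' ratio of genome to panel mutational opportunity (trinucleotide frequency
#' of the sequenced territory), then renormalized to a probability profile.
#'
#' @param cat An [sbs_catalogue()].
#' @param panel,genome Opportunity vectors: 32 positive frequencies named by
#'   [opportunity_contexts()] (pyrimidine-centred; purine contexts must be
#'   folded before lookup).
#' @return A 96-channel probability profile (named numeric, sums to 1).
#' @export
normalize_to_genome <- function(cat, panel, genome) {
  panel <- .check_opportunity(panel); genome <- .check_opportunity(genome)
  ctx <- sbs_channels()$context
  counts <- cat$counts
  zero_opp <- panel[ctx] <= 0 & counts > 0
  if (any(zero_opp))
    stop("degenerate opportunity: zero panel frequency for context(s) ",
         paste(unique(ctx[zero_opp]), collapse = ", "),
         " carrying observed counts", call. = FALSE)
  w <- counts * genome[ctx] / panel[ctx]
  w[counts == 0] <- 0
  if (sum(w) == 0) stop("empty catalogue cannot be normalized", call. = FALSE)
  stats::setNames(as.numeric(w / sum(w)), channel_labels())
}

.check_opportunity <- function(opp) {
  if (is.null(names(opp)) && length(opp) == 32L)
    names(opp) <- opportunity_contexts()
  if (!all(opportunity_contexts() %in% names(opp)))
    stop("opportunity vector must cover the 32 pyrimidine-centred contexts",
         call. = FALSE)
  opp[opportunity_contexts()]
}

#' Drop the T>C channels (80-channel spectrum)
#'
#' Removes the 16 T>C channels from a 96-channel vector; used when
#' batch-related T>C artefacts of unknown origin are suspected.
#'
#' @param vec Numeric 96-vector (counts or probabilities), or an
#'   [sbs_catalogue()].
#' @param renormalize Rescale the remaining 80 entries to sum to 1.
#' @return An 80-vector named by the retained channel labels.
#' @export
reduce_to_80c <- function(vec, renormalize = FALSE) {
  v <- if (inherits(vec, "sbs_catalogue")) vec$counts else vec
  if (length(v) != 96L) stop("expected a 96-channel vector", call. = FALSE)
  keep <- channel_mask("NON_TC")
  out <- stats::setNames(as.numeric(v[keep]), channel_labels()[keep])
  if (renormalize) {
    s <- sum(out)
    if (s == 0)
      stop("all mass on T>C channels: cannot renormalize 80c spectrum",
           call. = FALSE)
    out <- out / s
  }
  out
}

#' Re-embed an 80-channel vector into 96 channels with zero T>C mass
#' @param vec80 Numeric 80-vector in retained-channel order.
#' @return Named 96-vector with zeros at the T>C channels.
#' @export
expand_from_80c <- function(vec80) {
  if (length(vec80) != 80L) stop("expected an 80-channel vector", call. = FALSE)
  out <- stats::setNames(numeric(96), channel_labels())
  out[channel_mask("NON_TC")] <- as.numeric(vec80)
  out
}
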