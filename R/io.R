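#' Read per-sample SBS catalogues from a COSMIC-layout TSV
#'
#' Expected layout: a `MutationType` column of canonical channel labels plus
#' one column per sample. Rows may appear in any order; they are re-sorted
#' into canonical channel order.
#'
#' @param path TSV file path.
#' @param sample Optional sample (column) name; default reads all.
#' @return A single [sbs_catalogue()] if `sample` is given, otherwise a named
#'   list of catalogues.
#' @export
read_catalogue_tsv <- function(path, sample = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  type_col <- intersect(c("MutationType", "Type", "MutationsType"), names(df))[1]
  if (is.na(type_col))
    stop("no 'MutationType' column in ", path, call. = FALSE)
  missing <- setdiff(channel_labels(), df[[type_col]])
  if (length(missing))
    stop("catalogue TSV is missing ", length(missing), " channel(s), e.g. ",
         missing[1], call. = FALSE)
  rownames(df) <- df[[type_col]]
  df <- df[channel_labels(), setdiff(names(df), type_col), drop = FALSE]
  cats <- lapply(names(df), function(s) sbs_catalogue(df[[s]], sample_id = s))
  names(cats) <- names(df)
  if (!is.null(sample)) {
    if (!sample %in% names(cats))
      stop("sample '", sample, "' not found in ", path, call. = FALSE)
    return(cats[[sample]])
  }
  cats
}

#' Write catalogues to a COSMIC-layout TSV
#' @param cats An [sbs_catalogue()] or list of them.
#' @param path Output TSV path.
#' @export
write_catalogue_tsv <- function(cats, path) {
  if (inherits(cats, "sbs_catalogue")) cats <- list(cats)
  df <- data.frame(MutationType = channel_labels(), check.names = FALSE)
  for (ct in cats) df[[ct$sample_id]] <- as.numeric(ct$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix in COSMIC TSV layout
#'
#' A `Type` column of channel labels plus one column per signature; each
#' signature column must sum to 1 (checked to `tol`).
#'
#' @param path TSV file path.
#' @param tol Tolerance on column sums.
#' @return A 96 x k numeric matrix, rows in canonical channel order.
#' @export
read_signature_tsv <- function(path, tol = 1e-3) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  type_col <- intersect(c("Type", "MutationType"), names(df))[1]
  if (is.na(type_col)) stop("no 'Type' column in ", path, call. = FALSE)
  rownames(df) <- df[[type_col]]
  df <- df[channel_labels(), setdiff(names(df), type_col), drop = FALSE]
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  sums <- colSums(mat)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(mat)[off], collapse = ", "), call. = FALSE)
  rownames(mat) <- channel_labels()
  mat
}

#' Write a signature matrix in COSMIC TSV layout
#' @param mat Matrix with 96 rows (canonical order), one column per signature.
#' @param path Output path.
#' @export
write_signature_tsv <- function(mat, path) {
  df <- data.frame(Type = channel_labels(), check.names = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutational-opportunity table
#'
#' Two columns, `Context` and `Frequency`, one row per pyrimidine-centred
#' trinucleotide (32 rows).
#'
#' @param path TSV path.
#' @return Named numeric vector over [opportunity_contexts()].
#' @export
read_opportunity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("Context", "Frequency") %in% names(df)))
    stop("opportunity TSV needs 'Context' and 'Frequency' columns", call. = FALSE)
  opp <- stats::setNames(df$Frequency, df$Context)
  .check_opportunity(opp)
}

#' Build a catalogue from somatic SNVs in a VCF file
#'
#' Reads biallelic SNVs with `VariantAnnotation` and assigns channels using
#' trinucleotide context looked up in an indexed reference FASTA. Non-SNV
#' records are dropped with a message.
#'
#' @param vcf_path VCF 4.x file (SNVs used; others skipped).
#' @param fasta_path Reference FASTA (faidx index created if absent).
#' @param sample_id Catalogue sample id; defaults to the VCF basename.
#' @return An [sbs_catalogue()].
#' @export
catalogue_from_vcf <- function(vcf_path, fasta_path, sample_id = NULL) {
  for (pkg in c("VariantAnnotation", "Rsamtools", "Biostrings", "GenomicRanges", "IRanges"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package '", pkg, "' is required for VCF input", call. = FALSE)
  fa <- Rsamtools::FaFile(fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES & alt %in% BASES
  if (any(!snv))
    message("skipping ", sum(!snv), " non-SNV record(s)")
  rr <- rr[snv]; ref <- ref[snv]; alt <- alt[snv]
  if (length(rr) == 0L)
    return(build_catalogue(data.frame(), sample_id = sample_id %||% basename(vcf_path)))
  ctx_rng <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(rr),
    IRanges::IRanges(GenomicRanges::start(rr) - 1L, GenomicRanges::start(rr) + 1L)
  )
  ctx <- as.character(Rsamtools::scanFa(fa, ctx_rng))
  labels <- vapply(seq_along(ref), function(i)
    classify_variant(ref[i], alt[i], ctx[i])$label, character(1))
  build_catalogue(data.frame(channel = labels),
                  sample_id = sample_id %||% basename(vcf_path))
}
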