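#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.channel_table <- local({
  grid <- expand.grid(
    three_prime = BASES, five_prime = BASES, substitution = SUBSTITUTIONS,
    stringsAsFactors = FALSE
  )
  # COSMIC ordering: substitution blocks in canonical order, contexts
  # lexicographic by 5' base then 3' base within each block.
  grid <- grid[, c("substitution", "five_prime", "three_prime")]
  ref <- substr(grid$substitution, 1, 1)
  alt <- substr(grid$substitution, 3, 3)
  data.frame(
    index = seq_len(96L),
    substitution = grid$substitution,
    ref = ref,
    alt = alt,
    five_prime = grid$five_prime,
    three_prime = grid$three_prime,
    context = paste0(grid$five_prime, ref, grid$three_prime),
    label = paste0(grid$five_prime, "[", grid$substitution, "]", grid$three_prime),
    stringsAsFactors = FALSE
  )
})

#' Canonical SBS channel table
#'
#' The 96 single-base-substitution channels in COSMIC order: substitution
#' classes `C>A, C>G, C>T, T>A, T>C, T>G`, contexts lexicographic by 5' then
#' 3' flanking base within each class. The mutated base is always written on
#' the pyrimidine strand.
#'
#' @return A 96-row data frame with columns `index`, `substitution`, `ref`,
#'   `alt`, `five_prime`, `three_prime`, `context` and `label`
#'   (e.g. `"A[C>T]G"`).
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() .channel_table

#' All 96 canonical channel labels, in order
#' @return Character vector of length 96.
#' @export
channel_labels <- function() .channel_table$label

.context_32 <- unique(.channel_table$context)  # 16 NCN then 16 NTN

#' The 32 pyrimidine-centred trinucleotide contexts, in channel order
#' @return Character vector of length 32 (`ACA` ... `TCT`, `ATA` ... `TTT`).
#' @export
opportunity_contexts <- function() .context_32

#' Parse a canonical SBS channel label
#'
#' @param label Channel string of the form `"X[R>A]Y"`, pyrimidine-centred.
#' @return A one-row data frame as in [sbs_channels()], including the
#'   canonical `index`.
#' @export
#' @examples
#' parse_channel("A[C>T]G")$index
parse_channel <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", label))[[1]]
  if (length(m) == 0L)
    stop("malformed channel label: '", label, "'", call. = FALSE)
  ref <- m[3]; alt <- m[4]
  if (!ref %in% c("C", "T"))
    stop("purine-centred channel label: '", label,
         "' (central base must be C or T)", call. = FALSE)
  if (ref == alt)
    stop("reference and alternate base identical in '", label, "'", call. = FALSE)
  .channel_table[.channel_table$label == label, , drop = FALSE]
}

#' Reverse-complement a DNA string
#' @param x Character scalar over ACGT.
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  paste(rev(COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}

#' Channel masks over the 96 SBS channels
#'
#' Named index subsets used throughout: `CT` (the 16 C>T channels), `TC`
#' (the 16 T>C channels), `NON_TC` (the 80 channels remaining after T>C
#' removal) and `ALL`.
#'
#' @param name One of `"CT"`, `"TC"`, `"NON_TC"`, `"ALL"`.
#' @return Sorted integer indices into the 96-channel vector.
#' @export
#' @examples
#' length(channel_mask("NON_TC"))
channel_mask <- function(name = c("ALL", "CT", "TC", "NON_TC")) {
  name <- match.arg(name)
  switch(name,
    ALL = 1:96,
    CT = which(.channel_table$substitution == "C>T"),
    TC = which(.channel_table$substitution == "T>C"),
    NON_TC = which(.channel_table$substitution != "T>C")
  )
}

#' Cosine similarity on a channel subset
#'
#' @param a,b Numeric vectors of equal length.
#' @param mask Integer indices (or a mask name accepted by [channel_mask()])
#'   selecting the sub-vectors compared. Default compares full vectors.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_sim(c(1, 1, 0), c(1, 0, 0))
cosine_sim <- function(a, b, mask = NULL) {
  stopifnot(length(a) == length(b))
  if (is.character(mask)) {
    idx <- channel_mask(mask)
    if (length(a) == 80L) {  # vectors already reduced to the non-T>C set
      keep <- channel_mask("NON_TC")
      idx <- match(intersect(idx, keep), keep)
    }
    mask <- idx
  }
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined: zero vector within mask", call. = FALSE)
  sum(a * b) / (na * nb)
}
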