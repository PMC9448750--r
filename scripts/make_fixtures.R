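# Regenerates the packaged synthetic signature fixtures under inst/extdata/.
# All recipes are deterministic (no RNG); run from the repository root:
#   Rscript scripts/make_fixtures.R
suppressMessages(pkgload::load_all(".", quiet = TRUE))

ch <- sbs_channels()
lbl <- channel_labels()
blank <- setNames(numeric(96), lbl)

ct_idx <- channel_mask("CT")
ct_five <- ch$five_prime[ct_idx]
ct_three <- ch$three_prime[ct_idx]

# --- FFPE artefact signatures (synthetic stand-ins) ------------------------
# Unrepaired: cytosine deamination at any C -> broad C>T with mild
# context preferences (depleted at CpG, favoured by A/T-rich flanks).
five_mult <- c(A = 1.1, C = 0.9, G = 0.8, T = 1.2)
three_mult <- c(A = 1.2, C = 0.8, G = 0.6, T = 1.4)
unrep <- blank
unrep[ct_idx] <- five_mult[ct_five] * three_mult[ct_three]
unrep <- unrep / sum(unrep)

# Repaired: UDG removes uracil, leaving only 5mC-derived artefacts at CpG
# (NCG contexts), with a small unrepaired residue elsewhere.
rep_sig <- blank
rep_sig[c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")] <- c(0.11, 0.08, 0.06, 0.62)
non_cpg_ct <- ct_idx[ct_three != "G"]
rep_sig[non_cpg_ct] <- 0.13 / length(non_cpg_ct)
rep_sig <- rep_sig / sum(rep_sig)

write_signature_tsv(cbind(unrepaired = unrep, repaired = rep_sig),
                    "inst/extdata/synthetic_ffpe_signatures.tsv")

# --- Reference signature set (synthetic stand-ins) -------------------------
# SBS1like: clock-like CpG C>T spikes; small flat residue outside C>T/T>C.
sbs1 <- blank
sbs1[c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")] <- c(0.082, 0.060, 0.048, 0.660)
sbs1[non_cpg_ct] <- 0.10 / length(non_cpg_ct)
other <- setdiff(seq_len(96), c(ct_idx, channel_mask("TC")))
sbs1[other] <- sbs1[other] + 0.05 / length(other)
sbs1 <- sbs1 / sum(sbs1)

# SBS5like: featureless flat signature over all 96 channels.
sbs5 <- setNames(rep(1 / 96, 96), lbl)

# SBS18like: reactive-oxygen-species damage, C>A dominant.
ca_idx <- which(ch$substitution == "C>A")
sbs18 <- blank
sbs18[ca_idx] <- 0.85 * {
  w <- c(A = 1.0, C = 1.2, G = 0.8, T = 1.0)[ch$five_prime[ca_idx]] *
       c(A = 1.3, C = 0.7, G = 0.9, T = 1.1)[ch$three_prime[ca_idx]]
  w / sum(w)
}
cg_ct <- which(ch$substitution %in% c("C>G", "C>T"))
sbs18[cg_ct] <- 0.15 / length(cg_ct)
sbs18 <- sbs18 / sum(sbs18)

# SBS40like: flat with a smooth tilt; deliberately confusable with SBS5like.
sbs40 <- 1 + 0.5 * sin(2 * pi * seq_len(96) / 96)
sbs40 <- setNames(sbs40 / sum(sbs40), lbl)

write_signature_tsv(
  cbind(SBS1like = sbs1, SBS5like = sbs5, SBS18like = sbs18, SBS40like = sbs40),
  "inst/extdata/synthetic_reference_signatures.tsv")

# --- Example opportunity tables -------------------------------------------
# A synthetic targeted panel depleted in CpG-containing contexts relative to
# a flat genome, for exercising panel -> genome projection.
ctx <- opportunity_contexts()
genome <- setNames(rep(1 / 32, 32), ctx)
panel <- genome * ifelse(grepl("CG", ctx), 0.4, 1.3)
panel <- panel / sum(panel)
write.table(data.frame(Context = ctx, Frequency = genome),
            "inst/extdata/synthetic_genome_opportunity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(Context = ctx, Frequency = panel),
            "inst/extdata/synthetic_panel_opportunity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written to inst/extdata/\n")
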