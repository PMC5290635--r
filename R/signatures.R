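# Substitution spectra, hypermutation flagging and MMR-gene screening.
#
# Spectra follow the standard pyrimidine-strand convention: a substitution
# whose reference base is a purine (A or G) is collapsed to its reverse
# complement, so every SNV falls into one of six classes
# (C>A, C>G, C>T, T>A, T>C, T>G). The 96-class spectrum additionally keys
# on the 5' and 3' flanking bases of the (collapsed) context.

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

context96_keys <- function() {
  bases <- c("A", "C", "G", "T")
  keys <- character(0)
  for (cl in SPECTRUM_CLASSES)
    for (b5 in bases)
      for (b3 in bases)
        keys <- c(keys, paste0(b5, "[", cl, "]", b3))
  keys
}

# collapse SNVs to the pyrimidine strand; returns class, and the collapsed
# context when a valid 3-mer context is present
collapse_snv <- function(ref, alt, context) {
  purine <- ref %in% c("A", "G")
  cref <- ifelse(purine, unname(DNA_COMP[ref]), ref)
  calt <- ifelse(purine, unname(DNA_COMP[alt]), alt)
  has_ctx <- nchar(context) == 3L & substr(context, 2, 2) == ref
  cctx <- context
  cctx[purine & has_ctx] <- revcomp(context[purine & has_ctx])
  cctx[!has_ctx] <- ""
  data.frame(class6 = paste0(cref, ">", calt), context = cctx,
             valid_context = has_ctx)
}

#' Compute the 6-class and 96-class substitution spectrum
#'
#' Non-SNVs are ignored (their count is reported); purine-reference SNVs
#' are collapsed to the pyrimidine strand with reverse-complemented
#' context. The 96-class spectrum uses only variants whose context is a
#' valid 3-mer with the reference base in the middle; inconsistent contexts
#' are excluded from `counts96` only (with a warning).
#'
#' @param variants a [somatic_variants()] data.frame.
#' @return object of class `mutation_spectrum`: `counts6` (named integer
#'   vector over the six classes), `counts96` (named vector over
#'   `5'[class]3'` keys, all-zero when no contexts are available), `n_snv`,
#'   `ct_fraction` (`C>T` share of SNVs; `NA` when `n_snv` is 0),
#'   `n_ignored_non_snv`, `n_bad_context`.
#' @examples
#' v <- somatic_variants(data.frame(
#'   sample_id = "S1", chrom = "chr1", pos = 1:2, ref = c("G", "C"),
#'   alt = c("A", "T"), ref_count = 10, alt_count = 10,
#'   context = c("TGA", "ACG")))
#' mutation_spectrum(v)
#' @export
mutation_spectrum <- function(variants) {
  v <- somatic_variants(variants)
  snv <- is_snv(v$ref, v$alt)
  n_ignored <- sum(!snv)
  v <- v[snv, , drop = FALSE]
  counts6 <- setNames(integer(6), SPECTRUM_CLASSES)
  counts96 <- setNames(integer(96), context96_keys())
  n_bad <- 0L
  if (nrow(v)) {
    cc <- collapse_snv(v$ref, v$alt, v$context)
    t6 <- table(factor(cc$class6, levels = SPECTRUM_CLASSES))
    counts6[names(t6)] <- as.integer(t6)
    bad <- nzchar(v$context) & !cc$valid_context
    n_bad <- sum(bad)
    if (n_bad) warning(n_bad, " variant(s) with context inconsistent with ref; ",
                       "excluded from the 96-class spectrum")
    with_ctx <- cc$valid_context
    if (any(with_ctx)) {
      keys <- paste0(substr(cc$context[with_ctx], 1, 1), "[",
                     cc$class6[with_ctx], "]",
                     substr(cc$context[with_ctx], 3, 3))
      t96 <- table(factor(keys, levels = context96_keys()))
      counts96[names(t96)] <- as.integer(t96)
    }
  }
  n_snv <- sum(counts6)
  structure(list(counts6 = counts6, counts96 = counts96, n_snv = n_snv,
                 ct_fraction = if (n_snv > 0) unname(counts6["C>T"]) / n_snv
                               else NA_real_,
                 n_ignored_non_snv = n_ignored, n_bad_context = n_bad),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("Mutation spectrum over %d SNVs (%d non-SNV ignored)\n",
              x$n_snv, x$n_ignored_non_snv))
  print(x$counts6)
  if (!is.na(x$ct_fraction))
    cat(sprintf("C>T fraction: %.3f (%d%%)\n", x$ct_fraction,
                as.integer(round_half_away(100 * x$ct_fraction))))
  invisible(x)
}

#' Flag a hypermutated sample from its coding mutation burden
#'
#' Counts coding SNVs and compares against a fixed threshold (default 500,
#' chosen to separate hypermutated tumors with thousands of coding
#' mutations from typical exomes with tens). Also reports the burden per
#' megabase of capture territory.
#'
#' @param variants a [somatic_variants()] data.frame for one sample.
#' @param threshold coding-SNV count at or above which the sample is
#'   flagged (default 500).
#' @param capture_mb size of the captured coding territory in Mb
#'   (default 30).
#' @param mmr_genes genes screened for non-synonymous hits (default the
#'   mismatch-repair core: MLH1, MSH2, MSH6, PMS2).
#' @return list with `coding_snv_count`, `mut_per_mb`, `is_hypermutated`,
#'   `mmr_hits` (data.frame from [screen_mmr()]).
#' @export
flag_hypermutation <- function(variants, threshold = 500, capture_mb = 30,
                               mmr_genes = c("MLH1", "MSH2", "MSH6", "PMS2")) {
  if (capture_mb <= 0) stopf("capture_mb must be > 0")
  v <- somatic_variants(variants)
  n_coding <- sum(v$coding & is_snv(v$ref, v$alt))
  list(coding_snv_count = n_coding,
       mut_per_mb = n_coding / capture_mb,
       is_hypermutated = n_coding >= threshold,
       mmr_hits = screen_mmr(v, mmr_genes))
}

#' Screen variants for non-synonymous hits in mismatch-repair genes
#'
#' @param variants a [somatic_variants()] data.frame.
#' @param gene_list gene symbols to screen (default MLH1, MSH2, MSH6,
#'   PMS2).
#' @return the matching rows (missense, nonsense, frameshift or splice
#'   variants in listed genes).
#' @export
screen_mmr <- function(variants, gene_list = c("MLH1", "MSH2", "MSH6", "PMS2")) {
  v <- somatic_variants(variants)
  hit <- v$gene %in% gene_list &
    v$effect %in% c("missense", "nonsense", "frameshift", "splice")
  out <- v[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
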