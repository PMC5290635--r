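# Builders for tiny in-code fixtures shared across test files.

make_variants <- function(chrom = "chr1", pos = seq_along(ref), ref = "C",
                          alt = "T", ref_count = 60L, alt_count = 40L,
                          gene = "", effect = "other", coding = FALSE,
                          context = "", sample_id = "S1") {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(ref_count), length(alt_count), length(gene),
           length(effect), length(context))
  somatic_variants(data.frame(
    sample_id = sample_id, chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    ref_count = rep_len(ref_count, n), alt_count = rep_len(alt_count, n),
    gene = rep_len(gene, n), effect = rep_len(effect, n),
    coding = rep_len(coding, n), context = rep_len(context, n)))
}

write_vcf_lines <- function(body, path, sample = "S1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Context\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    body), path)
  path
}

make_segments <- function(chrom, start, end, total_cn, laf = NA_real_,
                          sample_id = "S1") {
  validate_segments(data.frame(sample_id = sample_id, chrom = chrom,
                               start = start, end = end,
                               total_cn = total_cn, laf = laf))
}

make_breakpoints <- function(chrom_a, pos_a, chrom_b, pos_b, support,
                             sample_id = "S1") {
  canonical_breakpoints(data.frame(sample_id = rep_len(sample_id, length(chrom_a)),
                                   chrom_a = chrom_a, pos_a = pos_a,
                                   chrom_b = chrom_b, pos_b = pos_b,
                                   support = support))
}

# two well-separated 3-D Gaussian blobs with known labels
two_blob_data <- function(n_each = 200, sep = 5, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_each * 3, 0, sd), ncol = 3),
               matrix(rnorm(n_each * 3, sep * sd, sd), ncol = 3))
    list(x = x, labels = rep(1:2, each = n_each))
  })
}

# fraction of rows whose hard assignment matches the truth, maximized over
# the label permutation (binary case)
binary_accuracy <- function(assign, labels) {
  a <- mean((assign == 1) == (labels == 1))
  max(a, 1 - a)
}
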