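#' @importFrom stats dist kmeans rbinom rmultinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome names to the "chr"-prefixed form
#'
#' Accepts names with or without the `chr` prefix (`"7"`, `"chr7"`) and
#' returns the prefixed form. Mitochondrial `MT` is mapped to `chrM`.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @examples
#' norm_chrom(c("7", "chrX", "MT"))
#' @export
norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom == "MT"] <- "M"
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Variant key string
#'
#' Canonical `chrom:pos:ref:alt` key used to match mutations across
#' timepoints.
#'
#' @param chrom,pos,ref,alt vectors describing variants (recycled).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch) {
    paste(rev(unname(DNA_COMP[ch])), collapse = "")
  }, character(1))
}

is_snv <- function(ref, alt) nchar(ref) == 1L & nchar(alt) == 1L &
  ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

EFFECT_LEVELS <- c("missense", "nonsense", "synonymous", "frameshift",
                   "splice", "noncoding", "other")

#' Construct / validate a somatic variant table
#'
#' The package-wide container for somatic calls is a plain `data.frame`
#' with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#' `alt_count`, `gene`, `effect`, `coding`, `context`. This constructor
#' fills optional columns, normalizes chromosome names and checks the
#' invariants (non-negative counts, valid effect vocabulary, context midbase
#' equal to the reference base for SNVs).
#'
#' @param df data.frame with at least `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`.
#' @return validated data.frame with a `vaf` column (`NA` at zero depth).
#' @export
somatic_variants <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing variant columns: %s", paste(miss, collapse = ", "))
  df$chrom <- norm_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  n <- nrow(df)
  if (is.null(df$gene)) df$gene <- rep("", n)
  if (is.null(df$effect)) df$effect <- rep("other", n)
  if (is.null(df$coding)) df$coding <- rep(FALSE, n)
  if (is.null(df$context)) df$context <- rep("", n)
  bad_eff <- !df$effect %in% EFFECT_LEVELS
  if (any(bad_eff)) stopf("invalid effect value(s): %s",
                          paste(unique(df$effect[bad_eff]), collapse = ", "))
  if (any(df$ref_count < 0 | df$alt_count < 0)) stopf("negative allele counts")
  has_ctx <- nzchar(df$context)
  if (any(has_ctx & nchar(df$context) != 3L))
    stopf("context must be a 3-base string or empty")
  snv <- is_snv(df$ref, df$alt)
  mid <- substr(df$context, 2, 2)
  bad_ctx <- has_ctx & snv & mid != df$ref
  if (any(bad_ctx))
    warning(sum(bad_ctx), " variant(s) with context middle base != ref")
  depth <- df$ref_count + df$alt_count
  df$vaf <- ifelse(depth > 0, df$alt_count / depth, NA_real_)
  rownames(df) <- NULL
  df[c(need, "gene", "effect", "coding", "context", "vaf")]
}
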