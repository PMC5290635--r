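# Readers/writers for the standard formats the pipeline touches:
# somatic VCF (FORMAT AD; INFO GENE/EFFECT/TNC), SEG-like copy-number TSV,
# BEDPE breakpoints, and JSON/TSV result reports.

coding_effects <- c("missense", "nonsense", "synonymous", "frameshift", "splice")

# light structural validation so parse errors can name the offending line
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stopf("malformed VCF '%s': no #CHROM header line", path)
  body <- setdiff(seq_along(lines), c(grep("^#", lines)))
  for (i in body) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 10)
      stopf("malformed VCF '%s' at line %d: %d fields (expected >= 10)", path, i, nf)
  }
  invisible(TRUE)
}

#' Read somatic calls for one sample from a VCF
#'
#' Parses a VCF v4.2 with per-sample allele depths (`FORMAT` field `AD`)
#' and optional `INFO` keys `GENE`, `EFFECT` and `TNC` (trinucleotide
#' context of the reference strand). Multi-allelic records are split into
#' one variant per ALT allele. Positions stay 1-based; chromosome names are
#' normalized to the `chr` prefix.
#'
#' @param path path to a VCF file.
#' @param sample_id sample column to extract; must exist in the VCF.
#' @return a [somatic_variants()] data.frame (possibly 0-row).
#' @seealso [write_somatic_vcf()] for the inverse.
#' @export
read_somatic_vcf <- function(path, sample_id) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  validate_vcf_lines(path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("malformed VCF '%s': %s", path, conditionMessage(e)))
  gt <- vcf@gt
  if (is.null(gt) || !sample_id %in% colnames(gt))
    stopf("sample column '%s' not present in %s", sample_id, path)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))   # single record: named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  empty <- somatic_variants(data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(),
    ref_count = integer(), alt_count = integer()))
  if (is.null(fix) || nrow(fix) == 0) return(empty)
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample_id]
  gene <- vcfR::extract.info(vcf, element = "GENE")
  effect <- vcfR::extract.info(vcf, element = "EFFECT")
  tnc <- vcfR::extract.info(vcf, element = "TNC")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(ad[i]))
      stopf("VCF record %s:%s lacks AD for sample %s", fix[i, "CHROM"], fix[i, "POS"], sample_id)
    depths <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if (anyNA(depths) || length(depths) != length(alts) + 1L)
      stopf("VCF record %s:%s has malformed AD '%s'", fix[i, "CHROM"], fix[i, "POS"], ad[i])
    out[[i]] <- data.frame(
      row.names = NULL,
      sample_id = sample_id,
      chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]),
      alt = unname(alts),
      ref_count = depths[1],
      alt_count = depths[-1],
      gene = if (is.na(gene[i])) "" else unname(gene[i]),
      effect = if (is.na(effect[i])) "other" else unname(effect[i]),
      context = if (is.na(tnc[i])) "" else unname(tnc[i]))
  }
  df <- do.call(rbind, out)
  df$coding <- df$effect %in% coding_effects
  df <- somatic_variants(df)
  df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
}

#' Write somatic variants as a minimal VCF v4.2
#'
#' One record per variant (multi-allelic sites are not re-merged), with
#' `GT:AD` genotype fields and `GENE`/`EFFECT`/`TNC` INFO keys when present.
#' Round-trips through [read_somatic_vcf()] preserving chrom/pos/ref/alt/AD.
#'
#' @param variants a [somatic_variants()] data.frame for a single sample.
#' @param path output path.
#' @param sample_id sample column name; defaults to the table's sample id.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(variants, path, sample_id = NULL) {
  v <- somatic_variants(variants)
  sample_id <- sample_id %||% (if (nrow(v)) v$sample_id[1] else "SAMPLE")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect class\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context on the reference strand\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  if (nrow(v)) {
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
    info <- vapply(seq_len(nrow(v)), function(i) {
      parts <- character(0)
      if (nzchar(v$gene[i])) parts <- c(parts, paste0("GENE=", v$gene[i]))
      if (nzchar(v$effect[i])) parts <- c(parts, paste0("EFFECT=", v$effect[i]))
      if (nzchar(v$context[i])) parts <- c(parts, paste0("TNC=", v$context[i]))
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                  "GT:AD", paste0("0/1:", v$ref_count, ",", v$alt_count),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read copy-number segments from a SEG-like TSV
#'
#' Expects a header `sample`, `chrom`, `start`, `end`, `total_cn` and an
#' optional `laf` (lesser-allele frequency) column; coordinates are 1-based
#' inclusive. Segments are validated (no overlap within a sample and
#' chromosome, `start <= end`, `total_cn >= 0`, `laf` in [0, 0.5]) and
#' returned sorted by sample, chromosome and start.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `total_cn`, `laf` (`NA` when absent).
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("segment file %s missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  seg <- data.frame(sample_id = as.character(df$sample),
                    chrom = norm_chrom(df$chrom),
                    start = as.integer(df$start), end = as.integer(df$end),
                    total_cn = as.numeric(df$total_cn),
                    laf = if ("laf" %in% names(df)) as.numeric(df$laf) else NA_real_)
  validate_segments(seg)
}

#' @rdname read_segments
#' @param seg a segment data.frame to validate and sort.
#' @export
validate_segments <- function(seg) {
  if (any(seg$start > seg$end)) stopf("segment with start > end")
  if (any(seg$total_cn < 0)) stopf("negative copy number")
  if (any(!is.na(seg$laf) & (seg$laf < 0 | seg$laf > 0.5)))
    stopf("laf outside [0, 0.5]")
  seg <- seg[order(seg$sample_id, seg$chrom, seg$start), , drop = FALSE]
  for (key in unique(paste(seg$sample_id, seg$chrom))) {
    s <- seg[paste(seg$sample_id, seg$chrom) == key, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stopf("overlapping segments for %s", key)
  }
  rownames(seg) <- NULL
  seg
}

#' @rdname read_segments
#' @param path output path for `write_segments`.
#' @export
write_segments <- function(seg, path) {
  seg <- validate_segments(seg)
  out <- data.frame(sample = seg$sample_id, chrom = seg$chrom,
                    start = seg$start, end = seg$end,
                    total_cn = seg$total_cn, laf = seg$laf)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read structural-variant breakpoints from a BEDPE file
#'
#' BEDPE start columns are 0-based half-open on disk and converted to
#' 1-based in memory (`pos = start + 1`); the score column carries the
#' number of supporting reads. Junction ends are stored in canonical order
#' (`(chrom_a, pos_a) <= (chrom_b, pos_b)`) and the `kind` column is
#' derived (`intra` iff both ends share a chromosome).
#'
#' @param path path to a BEDPE file (no header; columns chrom1, start1,
#'   end1, chrom2, start2, end2, name, score). The name column, when not
#'   `"."`, carries the sample id.
#' @param sample_id sample label attached to every breakpoint; by default
#'   taken from the name column (falling back to `"sample"`).
#' @return data.frame with columns `sample_id`, `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `support`, `kind`.
#' @export
read_breakpoints <- function(path, sample_id = NULL) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first) || !nzchar(first))
    return(canonical_breakpoints(data.frame(
      sample_id = character(), chrom_a = character(), pos_a = integer(),
      chrom_b = character(), pos_b = integer(), support = integer())))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8) stopf("BEDPE %s has %d columns (expected >= 8)", path, ncol(df))
  if (any(df[[2]] < 0 | df[[5]] < 0)) stopf("negative coordinates in %s", path)
  support <- suppressWarnings(as.numeric(df[[8]]))
  if (anyNA(support) || any(support != round(support)))
    stopf("non-integer score column in %s", path)
  if (any(support < 0)) stopf("negative support in %s", path)
  name_col <- as.character(df[[7]])
  sid <- sample_id %||% ifelse(name_col == "." | !nzchar(name_col),
                               "sample", name_col)
  canonical_breakpoints(data.frame(
    sample_id = sid,
    chrom_a = norm_chrom(df[[1]]), pos_a = as.integer(df[[2]]) + 1L,
    chrom_b = norm_chrom(df[[4]]), pos_b = as.integer(df[[5]]) + 1L,
    support = as.integer(support)))
}

#' @rdname read_breakpoints
#' @param bp a breakpoint data.frame to canonicalize (ends ordered, `kind`
#'   derived, rows sorted).
#' @export
canonical_breakpoints <- function(bp) {
  if (nrow(bp)) {
    swap <- bp$chrom_a > bp$chrom_b |
      (bp$chrom_a == bp$chrom_b & bp$pos_a > bp$pos_b)
    if (any(swap)) {
      tmp_c <- bp$chrom_a[swap]; tmp_p <- bp$pos_a[swap]
      bp$chrom_a[swap] <- bp$chrom_b[swap]; bp$pos_a[swap] <- bp$pos_b[swap]
      bp$chrom_b[swap] <- tmp_c; bp$pos_b[swap] <- tmp_p
    }
  }
  bp$kind <- ifelse(bp$chrom_a == bp$chrom_b, "intra", "inter")
  bp <- bp[order(bp$sample_id, bp$chrom_a, bp$pos_a, bp$chrom_b, bp$pos_b), ,
           drop = FALSE]
  rownames(bp) <- NULL
  bp
}

#' @rdname read_breakpoints
#' @param path output path for `write_breakpoints` (positions written back
#'   as 0-based half-open intervals).
#' @export
write_breakpoints <- function(bp, path) {
  bp <- canonical_breakpoints(bp)
  out <- data.frame(bp$chrom_a, bp$pos_a - 1L, bp$pos_a,
                    bp$chrom_b, bp$pos_b - 1L, bp$pos_b,
                    bp$sample_id, bp$support)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# recursively sort names so emitted JSON is deterministic
sort_keys <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    x <- lapply(x, sort_keys)
  }
  x
}

write_json_report <- function(x, path) {
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Write a pipeline product as deterministic JSON (+ TSV twin where flat)
#'
#' Dispatches on the product class: CCF matrices get a TSV with one row per
#' mutation and one value/mask column pair per timepoint; cohort summaries
#' and patient reports get sorted-key JSON. Re-reading reproduces the
#' product (see [read_ccf_tsv()]).
#'
#' @param x a pipeline product (`longevol_ccf`, `cohort_summary`,
#'   `patient_report`, or any list).
#' @param path output path (extension chosen by the caller).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) UseMethod("write_report")

#' @export
write_report.default <- function(x, path) write_json_report(x, path)

#' @export
write_report.longevol_ccf <- function(x, path) {
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_report.cohort_summary <- function(x, path) {
  write_json_report(unclass(x), path)
}

#' @export
write_report.patient_report <- function(x, path) {
  write_json_report(patient_report_json(x), path)
}

#' Read a CCF matrix back from its TSV twin
#'
#' @param path path written by [write_report()] for a `longevol_ccf` object.
#' @return a `longevol_ccf` object.
#' @export
read_ccf_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tps <- as.integer(sub("^ccf_t", "", grep("^ccf_t", names(df), value = TRUE)))
  values <- as.matrix(df[paste0("ccf_t", tps)])
  mask <- as.matrix(df[paste0("mask_t", tps)])
  dimnames(values) <- dimnames(mask) <- list(df$key, paste0("t", tps))
  new_ccf_matrix(keys = df[c("key", "chrom", "pos", "ref", "alt")],
                 timepoints = tps, values = values, mask = mask,
                 multiplicity = as.matrix(df[paste0("mult_t", tps)]),
                 flagged = as.matrix(df[paste0("flag_t", tps)]))
}
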