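# Cancer-cell-fraction (clonality rate) estimation.
#
# Model: for a mutation present at multiplicity m in a fraction CCF of
# tumor cells, with tumor purity p, local tumor copy number cn_t and
# normal copy number cn_n,
#
#   E[VAF] = p * m * CCF / (p * cn_t + (1 - p) * cn_n)
#
# CCF is obtained by inverting this relation per variant.

#' Estimate mutation multiplicity from VAF, purity and local copy number
#'
#' The mutant-allele copy number per tumor cell, assuming the mutation is
#' clonal: `m = round(vaf * (purity * tumor_cn + (1 - purity) * normal_cn)
#' / purity)`, clipped to `[1, max(1, round(tumor_cn))]`. Ties at `x.5`
#' round half away from zero.
#'
#' @param vaf variant allele frequency in `[0, 1]`.
#' @param purity tumor cell fraction in `(0, 1]` (1 - admixture rate).
#' @param tumor_cn local total copy number in the tumor (>= 0).
#' @param normal_cn local copy number in normal cells (default 2).
#' @return integer multiplicity, vectorized over the inputs.
#' @examples
#' estimate_multiplicity(0.5, 1, 2)        # diploid clonal het -> 1
#' estimate_multiplicity(0.9, 0.8, 20)     # high-amplification locus
#' @export
estimate_multiplicity <- function(vaf, purity, tumor_cn, normal_cn = 2) {
  if (any(purity <= 0)) stopf("purity must be > 0")
  if (any(vaf < 0 | vaf > 1)) stopf("vaf outside [0, 1]")
  if (any(tumor_cn < 0)) stopf("tumor_cn must be >= 0")
  m <- round_half_away(vaf * (purity * tumor_cn + (1 - purity) * normal_cn) / purity)
  hi <- pmax(1, round_half_away(tumor_cn))
  as.integer(pmin(pmax(m, 1), hi))
}

#' Cancer cell fraction from VAF, purity, copy number and multiplicity
#'
#' Inverts the purity/ploidy VAF model. The raw value
#' `vaf * (purity * tumor_cn + (1 - purity) * normal_cn) /
#' (purity * multiplicity)` is capped at `ccf_cap` (default 1.5) and values
#' above 1.2 are flagged as inconsistent with the assumed copy state.
#'
#' @inheritParams estimate_multiplicity
#' @param multiplicity mutant-allele copies per tumor cell (>= 1).
#' @param ccf_cap cap applied before reporting (default 1.5).
#' @return data.frame with columns `ccf`, `ccf_raw`, `flagged_inconsistent`.
#' @examples
#' ccf_from_vaf(0.5, 1, 2, 1)    # fully clonal diploid het
#' ccf_from_vaf(0.1, 0.4, 2, 1)  # low-purity sample
#' @export
ccf_from_vaf <- function(vaf, purity, tumor_cn, multiplicity,
                         normal_cn = 2, ccf_cap = 1.5) {
  if (any(purity <= 0)) stopf("purity must be > 0")
  if (any(multiplicity < 1)) stopf("multiplicity must be >= 1")
  raw <- vaf * (purity * tumor_cn + (1 - purity) * normal_cn) /
    (purity * multiplicity)
  data.frame(ccf = pmin(raw, ccf_cap), ccf_raw = raw,
             flagged_inconsistent = raw > 1.2)
}

#' @rdname ccf_from_vaf
#' @param variant one row of a [somatic_variants()] table (depth must be
#'   positive).
#' @param meta one row of a sample metadata table with a `purity` column.
#' @details `compute_ccf()` is the per-variant wrapper used by the
#'   pipeline; `ccf_from_vaf()` is the vectorized core.
#' @export
compute_ccf <- function(variant, meta, tumor_cn, multiplicity,
                        normal_cn = 2, ccf_cap = 1.5) {
  depth <- variant$ref_count + variant$alt_count
  if (any(depth <= 0)) stopf("zero-depth variant has no defined VAF")
  res <- ccf_from_vaf(variant$alt_count / depth, meta$purity, tumor_cn,
                      multiplicity, normal_cn, ccf_cap)
  cbind(data.frame(key = variant_key(variant$chrom, variant$pos,
                                     variant$ref, variant$alt),
                   multiplicity = as.integer(multiplicity)),
        res)
}

# local total copy number at 1-based positions, from sorted non-overlapping
# segments of one sample
lookup_cn <- function(segments, chrom, pos, default_cn = NULL) {
  chrom <- norm_chrom(chrom)
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(s)) {
      j <- findInterval(pos[idx], s$start)
      hit <- j >= 1 & pos[idx] <= ifelse(j >= 1, s$end[pmax(j, 1)], -1)
      out[idx[hit]] <- s$total_cn[j[hit]]
    }
  }
  if (anyNA(out)) {
    if (is.null(default_cn))
      stopf("%d variant position(s) not covered by any segment and no default_cn set",
            sum(is.na(out)))
    out[is.na(out)] <- default_cn
  }
  out
}

new_ccf_matrix <- function(keys, timepoints, values, mask, multiplicity, flagged) {
  structure(list(keys = keys, timepoints = timepoints, values = values,
                 mask = mask, multiplicity = multiplicity, flagged = flagged),
            class = "longevol_ccf")
}

#' @export
as.data.frame.longevol_ccf <- function(x, ...) {
  df <- x$keys
  for (j in seq_along(x$timepoints)) {
    t <- x$timepoints[j]
    df[[paste0("ccf_t", t)]] <- x$values[, j]
    df[[paste0("mask_t", t)]] <- x$mask[, j]
    df[[paste0("mult_t", t)]] <- x$multiplicity[, j]
    df[[paste0("flag_t", t)]] <- x$flagged[, j]
  }
  df
}

#' @export
print.longevol_ccf <- function(x, ...) {
  cat(sprintf("CCF matrix: %d unique mutations x %d timepoints (%d usable for clustering)\n",
              nrow(x$values), ncol(x$values), sum(clustering_rows(x))))
  invisible(x)
}

#' Rows of a CCF matrix usable for clustering
#'
#' A mutation enters clustering only when every cell of its row is either
#' observed or confidently absent; any `absent_lowdepth` cell excludes it.
#'
#' @param x a `longevol_ccf` object.
#' @return logical vector over rows.
#' @export
clustering_rows <- function(x) {
  apply(x$mask != "absent_lowdepth", 1, all)
}

#' Assemble the multi-timepoint clonality (CCF) matrix
#'
#' Rows are the union of unique somatic mutations across timepoints. For
#' each timepoint a called mutation gets its estimated CCF (`observed`); an
#' uncalled mutation gets CCF 0 with mask `absent_confident` when the site
#' had depth `>= min_depth` in that sample, else `absent_lowdepth`.
#' Multiplicity is estimated per variant from the local copy number unless
#' provided in the variant table (`multiplicity` column).
#'
#' @param variants_by_timepoint named/ordered list of [somatic_variants()]
#'   tables, one per timepoint (ordered by timepoint).
#' @param segments_by_timepoint list of segment tables parallel to
#'   `variants_by_timepoint`.
#' @param metas data.frame with `sample_id`, `timepoint`, `purity` (and
#'   optionally `patient_id`, `subtype`) covering all timepoints.
#' @param min_depth minimum site depth for a confident absence (default 20).
#' @param depths_by_timepoint optional list of `chrom`/`pos`/`depth` tables
#'   giving sequencing depth at uncalled sites (e.g. from a pileup over the
#'   union of mutated positions). When `NULL`, every uncalled cell is
#'   masked `absent_lowdepth`.
#' @param normal_cn,ccf_cap,default_cn passed to the CCF model;
#'   `default_cn` (if non-`NULL`) substitutes for positions not covered by
#'   any segment instead of erroring.
#' @return a `longevol_ccf` object.
#' @export
assemble_ccf_matrix <- function(variants_by_timepoint, segments_by_timepoint,
                                metas, min_depth = 20,
                                depths_by_timepoint = NULL,
                                normal_cn = 2, ccf_cap = 1.5,
                                default_cn = NULL) {
  ntp <- length(variants_by_timepoint)
  if (ntp < 2) stopf("need >= 2 timepoints")
  if (length(segments_by_timepoint) != ntp)
    stopf("segments_by_timepoint must parallel variants_by_timepoint")
  metas <- metas[order(metas$timepoint), , drop = FALSE]
  if (anyDuplicated(metas$timepoint)) stopf("duplicate timepoints in metadata")
  if (nrow(metas) != ntp) stopf("metadata must cover all %d timepoints", ntp)
  tps <- metas$timepoint

  vs <- lapply(variants_by_timepoint, somatic_variants)
  keys_by_tp <- lapply(vs, function(v) variant_key(v$chrom, v$pos, v$ref, v$alt))
  for (j in seq_len(ntp)) {
    if (anyDuplicated(keys_by_tp[[j]]))
      stopf("duplicate variant key within timepoint %d: %s", tps[j],
            keys_by_tp[[j]][duplicated(keys_by_tp[[j]])][1])
  }
  all_keys <- sort(unique(unlist(keys_by_tp)))
  n <- length(all_keys)
  parts <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  keys <- data.frame(key = all_keys,
                     chrom = parts[, 1], pos = as.integer(parts[, 2]),
                     ref = parts[, 3], alt = parts[, 4],
                     stringsAsFactors = FALSE)

  values <- matrix(0, n, ntp, dimnames = list(all_keys, paste0("t", tps)))
  mult <- matrix(NA_integer_, n, ntp, dimnames = dimnames(values))
  flagged <- matrix(FALSE, n, ntp, dimnames = dimnames(values))
  mask <- matrix("absent_lowdepth", n, ntp, dimnames = dimnames(values))

  for (j in seq_len(ntp)) {
    v <- vs[[j]]
    purity <- metas$purity[j]
    if (nrow(v)) {
      depth <- v$ref_count + v$alt_count
      if (any(depth <= 0)) stopf("zero-depth call at timepoint %d", tps[j])
      cn <- lookup_cn(segments_by_timepoint[[j]], v$chrom, v$pos, default_cn)
      m <- if ("multiplicity" %in% names(v)) as.integer(v$multiplicity)
           else estimate_multiplicity(v$vaf, purity, cn, normal_cn)
      res <- ccf_from_vaf(v$vaf, purity, cn, m, normal_cn, ccf_cap)
      idx <- match(keys_by_tp[[j]], all_keys)
      values[idx, j] <- res$ccf
      mult[idx, j] <- m
      flagged[idx, j] <- res$flagged_inconsistent
      mask[idx, j] <- "observed"
    }
    # uncalled cells: confident absence needs adequate site depth
    uncalled <- mask[, j] != "observed"
    if (any(uncalled) && !is.null(depths_by_timepoint)) {
      dtab <- depths_by_timepoint[[j]]
      dkey <- paste(norm_chrom(dtab$chrom), dtab$pos)
      ukey <- paste(keys$chrom[uncalled], keys$pos[uncalled])
      d <- dtab$depth[match(ukey, dkey)]
      conf <- !is.na(d) & d >= min_depth
      mask[uncalled, j][conf] <- "absent_confident"
    }
  }
  new_ccf_matrix(keys, tps, values, mask, mult, flagged)
}
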