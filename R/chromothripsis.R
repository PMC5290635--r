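# Chromothripsis calling from copy-number oscillation plus clustered,
# high-read-support breakpoints; double-minute candidate extraction from
# the breakpoint graph; cohort summarization.

#' Default chromothripsis detector thresholds
#'
#' `support_min` (100 reads) and `amp_min` (copy number 20) are anchored to
#' the hallmark description of high-support intra-chromosomal breaks and
#' >20-copy amplified segments; `switch_min`, `break_min` and
#' `del_frac_min` operationalize copy-state oscillation, breakpoint
#' clustering and large-scale deletion. `merge_tol` is the slack (bp) when
#' matching breakpoint ends to amplified segments in the double-minute
#' graph.
#'
#' @param support_min minimum supporting reads for a breakpoint to count.
#' @param amp_min minimum rounded copy number of an amplified segment.
#' @param switch_min minimum copy-state switches on a chromosome.
#' @param break_min minimum supported breakpoints on a chromosome.
#' @param del_frac_min minimum fraction of covered length at CN <= 1 for a
#'   deleting event.
#' @param merge_tol breakpoint-end to segment matching tolerance in bp.
#' @return named list of thresholds.
#' @export
ct_params <- function(support_min = 100, amp_min = 20, switch_min = 10,
                      break_min = 10, del_frac_min = 0.3, merge_tol = 1e4) {
  list(support_min = support_min, amp_min = amp_min, switch_min = switch_min,
       break_min = break_min, del_frac_min = del_frac_min,
       merge_tol = merge_tol)
}

#' Per-chromosome copy-number / breakpoint features
#'
#' Copy numbers are rounded to the nearest integer before oscillation
#' counting so segmentation noise does not create spurious switches.
#'
#' @param segments segment table of one sample (see [read_segments()]).
#' @param breakpoints breakpoint table of the same sample.
#' @param chrom chromosome to profile.
#' @param support_min support threshold for a breakpoint to count
#'   (default 100).
#' @return one-row data.frame: `chrom`, `n_segments`, `n_switches`
#'   (adjacent segment pairs with different rounded copy state),
#'   `n_states`, `max_cn`, `frac_deleted` (fraction of covered length at
#'   rounded CN <= 1), `n_intra_supported`, `n_inter_supported` (supported
#'   inter-chromosomal links with an end on this chromosome), `laf_shift`
#'   (length-weighted mean |0.5 - laf|, `NA` when laf is absent).
#' @export
chromosome_features <- function(segments, breakpoints, chrom,
                                support_min = 100) {
  chrom <- norm_chrom(chrom)
  s <- segments[segments$chrom == chrom, , drop = FALSE]
  s <- s[order(s$start), , drop = FALSE]
  n_seg <- nrow(s)
  if (n_seg) {
    st <- round_half_away(s$total_cn)
    len <- s$end - s$start + 1
    n_switch <- if (n_seg > 1) sum(st[-1] != st[-n_seg]) else 0L
    frac_del <- sum(len[st <= 1]) / sum(len)
    laf_shift <- if (all(is.na(s$laf))) NA_real_ else {
      ok <- !is.na(s$laf)
      sum(abs(0.5 - s$laf[ok]) * len[ok]) / sum(len[ok])
    }
    max_cn <- max(s$total_cn)
    n_states <- length(unique(st))
  } else {
    n_switch <- 0L; frac_del <- 0; laf_shift <- NA_real_
    max_cn <- NA_real_; n_states <- 0L
  }
  bp <- breakpoints
  supported <- bp$support >= support_min
  intra <- bp$kind == "intra" & bp$chrom_a == chrom
  inter <- bp$kind == "inter" & (bp$chrom_a == chrom | bp$chrom_b == chrom)
  data.frame(chrom = chrom, n_segments = n_seg,
             n_switches = as.integer(n_switch), n_states = n_states,
             max_cn = max_cn, frac_deleted = frac_del,
             n_intra_supported = sum(intra & supported),
             n_inter_supported = sum(inter & supported),
             laf_shift = laf_shift)
}

#' Call chromothripsis events for one sample
#'
#' A chromosome is positive-amplifying when it oscillates
#' (`n_switches >= switch_min`), carries at least `break_min` supported
#' intra-chromosomal breakpoints and reaches `max_cn >= amp_min`. It is
#' positive-deleting when it oscillates, at least `del_frac_min` of its
#' covered length sits at rounded CN <= 1, and supported breakpoints
#' (intra plus incident inter links) reach `break_min`. Positive
#' chromosomes joined by at least one supported inter-chromosomal
#' breakpoint are merged into a single multi-chromosome call. The LAF
#' shift is reported as supporting evidence only and never gates a call.
#'
#' @param segments,breakpoints tables for one sample.
#' @param sample_id sample label (defaults to the tables' sample id).
#' @param params thresholds from [ct_params()].
#' @return list of calls; each call is a list with `sample_id`, `chroms`,
#'   `event_type` (`"amplifying"` if any member chromosome amplifies, else
#'   `"deleting"`), `features` (per-chromosome data.frame),
#'   `n_inter_links` (supported inter links between member chromosomes)
#'   and `dm_candidates` (see [dm_candidates()]).
#' @export
call_chromothripsis <- function(segments, breakpoints, sample_id = NULL,
                                params = ct_params()) {
  if ((is.null(segments) || nrow(segments) == 0)) return(list())
  sample_id <- sample_id %||% segments$sample_id[1]
  segments <- validate_segments(segments)
  breakpoints <- canonical_breakpoints(breakpoints)
  chroms <- sort(unique(segments$chrom))
  feats <- do.call(rbind, lapply(chroms, function(ch)
    chromosome_features(segments, breakpoints, ch, params$support_min)))
  amp_pos <- feats$n_switches >= params$switch_min &
    feats$n_intra_supported >= params$break_min &
    !is.na(feats$max_cn) & feats$max_cn >= params$amp_min
  del_pos <- feats$n_switches >= params$switch_min &
    (feats$n_intra_supported + feats$n_inter_supported) >= params$break_min &
    feats$frac_deleted >= params$del_frac_min
  pos <- amp_pos | del_pos
  if (!any(pos)) return(list())
  pos_chroms <- feats$chrom[pos]

  # join positive chromosomes linked by >= 1 supported inter breakpoint
  inter <- breakpoints[breakpoints$kind == "inter" &
                         breakpoints$support >= params$support_min, , drop = FALSE]
  inter <- inter[inter$chrom_a %in% pos_chroms & inter$chrom_b %in% pos_chroms, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(inter)) inter[, c("chrom_a", "chrom_b")] else
      data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = pos_chroms))
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(ci) {
    members <- sort(names(comp)[comp == ci])
    n_links <- sum(inter$chrom_a %in% members & inter$chrom_b %in% members)
    member_amp <- amp_pos[match(members, feats$chrom)]
    seg_sub <- segments[segments$chrom %in% members, , drop = FALSE]
    list(sample_id = sample_id,
         chroms = members,
         event_type = if (any(member_amp)) "amplifying" else "deleting",
         features = feats[feats$chrom %in% members, , drop = FALSE],
         n_inter_links = n_links,
         dm_candidates = dm_candidates(seg_sub, breakpoints,
                                       amp_min = params$amp_min,
                                       support_min = params$support_min,
                                       merge_tol = params$merge_tol))
  })
}

# does a position fall within tol of segment [start, end]?
pos_in_segment <- function(pos, start, end, tol) pos >= start - tol & pos <= end + tol

#' Extract double-minute candidate components from the breakpoint graph
#'
#' Nodes are segments with rounded copy number at least `amp_min`; edges
#' are supported breakpoints with both ends inside (or within `merge_tol`
#' of) node segments. Connected components with at least one edge are
#' returned — isolated high-copy segments are not candidates. Sequencing
#' alone cannot distinguish a double minute from a homogeneously staining
#' region, hence "candidates".
#'
#' @param segments,breakpoints tables for one sample.
#' @param amp_min minimum rounded copy number (default 20).
#' @param support_min minimum breakpoint read support (default 100).
#' @param merge_tol end-to-segment matching tolerance in bp (default 10 kb).
#' @return list of components; each has `segments` (data.frame),
#'   `linking_breakpoints` (data.frame) and `chroms` (character).
#' @export
dm_candidates <- function(segments, breakpoints, amp_min = 20,
                          support_min = 100, merge_tol = 1e4) {
  seg <- segments[round_half_away(segments$total_cn) >= amp_min, , drop = FALSE]
  if (!nrow(seg)) return(list())
  seg$node <- paste0(seg$chrom, ":", seg$start, "-", seg$end)
  bp <- breakpoints[breakpoints$support >= support_min, , drop = FALSE]
  edges <- NULL
  if (nrow(bp)) {
    for (i in seq_len(nrow(bp))) {
      a <- which(seg$chrom == bp$chrom_a[i] &
                   pos_in_segment(bp$pos_a[i], seg$start, seg$end, merge_tol))
      b <- which(seg$chrom == bp$chrom_b[i] &
                   pos_in_segment(bp$pos_b[i], seg$start, seg$end, merge_tol))
      if (length(a) && length(b))
        edges <- rbind(edges, data.frame(from = seg$node[a[1]],
                                         to = seg$node[b[1]], bp = i))
    }
  }
  if (is.null(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = seg$node))
  comp <- igraph::components(g)$membership
  out <- list()
  for (ci in sort(unique(comp))) {
    members <- names(comp)[comp == ci]
    e_idx <- edges$bp[edges$from %in% members & edges$to %in% members]
    if (!length(e_idx)) next   # singleton without incident breakpoint
    s <- seg[seg$node %in% members, setdiff(names(seg), "node"), drop = FALSE]
    rownames(s) <- NULL
    lb <- bp[sort(unique(e_idx)), , drop = FALSE]
    rownames(lb) <- NULL
    out[[length(out) + 1L]] <- list(segments = s, linking_breakpoints = lb,
                                    chroms = sort(unique(s$chrom)))
  }
  out
}

#' Summarize chromothripsis (and optionally hypermutation) over a cohort
#'
#' @param calls_by_sample named list: sample id -> list of calls from
#'   [call_chromothripsis()] (possibly empty).
#' @param metas data.frame with `sample_id` and `subtype` for every sample.
#' @param hyper_by_sample optional named logical vector: sample id ->
#'   hypermutation flag.
#' @return object of class `cohort_summary`: `per_subtype` (and
#'   `hypermutated` when flags given), each a map subtype ->
#'   `n_samples`, `n_positive`, `fraction`, `percent_text` (see
#'   [format_percent()]).
#' @export
summarize_cohort <- function(calls_by_sample, metas, hyper_by_sample = NULL) {
  ids <- names(calls_by_sample)
  miss <- setdiff(ids, metas$sample_id)
  if (length(miss)) stopf("sample(s) without metadata: %s",
                          paste(miss, collapse = ", "))
  subtype <- metas$subtype[match(ids, metas$sample_id)]
  positive <- vapply(calls_by_sample, function(x) length(x) > 0, logical(1))
  tally <- function(flag) {
    out <- list()
    for (st in sort(unique(subtype))) {
      n <- sum(subtype == st)
      np <- sum(flag[subtype == st])
      out[[st]] <- list(n_samples = n, n_positive = np, fraction = np / n,
                        percent_text = format_percent(np, n))
    }
    out
  }
  res <- list(per_subtype = tally(positive))
  if (!is.null(hyper_by_sample))
    res$hypermutated <- tally(as.logical(hyper_by_sample[ids]))
  structure(res, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort chromothripsis summary:\n")
  for (st in names(x$per_subtype)) {
    s <- x$per_subtype[[st]]
    cat(sprintf("  %s: %d/%d positive (%s)\n", st, s$n_positive, s$n_samples,
                s$percent_text))
  }
  invisible(x)
}
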