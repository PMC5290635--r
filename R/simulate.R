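# Synthetic-data generators: serial-tumor clonal evolution with binomial
# read sampling, chromothriptic vs quiet chromosomes, signature-skewed
# mutation sets, and a labeled cohort — each a pure function of
# (specification, seed), each paired with a truth table.

#' Specify a simulated clone
#'
#' @param clone_id integer clone label.
#' @param ccf_by_timepoint true cancer cell fraction at each timepoint,
#'   values in `[0, 1]`.
#' @param n_mutations number of mutations carried by the clone.
#' @param spectrum_profile 6-class substitution probabilities (named over
#'   `C>A, C>G, C>T, T>A, T>C, T>G`; must sum to 1).
#' @param coding_fraction fraction of the clone's mutations that are
#'   coding.
#' @return a `clone_spec` list.
#' @export
clone_spec <- function(clone_id, ccf_by_timepoint, n_mutations = 50,
                       spectrum_profile = baseline_spectrum(),
                       coding_fraction = 0.6) {
  stopifnot(all(ccf_by_timepoint >= 0 & ccf_by_timepoint <= 1),
            n_mutations >= 0,
            abs(sum(spectrum_profile) - 1) < 1e-9,
            coding_fraction >= 0, coding_fraction <= 1)
  structure(list(clone_id = clone_id, ccf_by_timepoint = ccf_by_timepoint,
                 n_mutations = n_mutations,
                 spectrum_profile = spectrum_profile,
                 coding_fraction = coding_fraction),
            class = "clone_spec")
}

#' @rdname clone_spec
#' @details `baseline_spectrum()` is a C>T-leaning exome-like profile
#'   (60% C>T); `alkylator_spectrum()` is the heavily C>T-skewed profile
#'   (97% C>T) characteristic of alkylating-agent exposure under MMR
#'   deficiency.
#' @export
baseline_spectrum <- function() {
  setNames(c(0.08, 0.06, 0.60, 0.06, 0.14, 0.06), SPECTRUM_CLASSES)
}

#' @rdname clone_spec
#' @export
alkylator_spectrum <- function() {
  setNames(c(0.006, 0.006, 0.97, 0.006, 0.006, 0.006), SPECTRUM_CLASSES)
}

#' Default three-timepoint clone set
#'
#' Four clones over three serial tumors: a preserved founding clone
#' (CCF 0.95 throughout), a clone lost after the first timepoint
#' (0.6, 0, 0), a subclone emerging at the second timepoint (0, 0.5, 0.5)
#' and a late subclone emerging at the third (0, 0, 0.45) carrying the
#' alkylator-skewed spectrum. With `hypermutated = TRUE` the late clone
#' instead carries 2079 all-coding mutations (a hypermutated second
#' recurrence) including one MSH6 missense mutation.
#'
#' @param n_mutations mutations per clone (default 50).
#' @param hypermutated plant a hypermutated late clone (default FALSE).
#' @return list of [clone_spec()] objects.
#' @export
default_clones <- function(n_mutations = 50, hypermutated = FALSE) {
  list(
    clone_spec(1, c(0.95, 0.95, 0.95), n_mutations),
    clone_spec(2, c(0.60, 0.00, 0.00), n_mutations),
    clone_spec(3, c(0.00, 0.50, 0.50), n_mutations),
    clone_spec(4, c(0.00, 0.00, 0.45),
               n_mutations = if (hypermutated) 2079 else n_mutations,
               spectrum_profile = alkylator_spectrum(),
               coding_fraction = if (hypermutated) 1 else 0.6))
}

# draw (ref, alt, context) consistent with a 6-class profile, with random
# strand presentation (pyrimidine or purine reference)
draw_snv_identities <- function(n, profile) {
  classes <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = profile)
  ref <- substr(classes, 1, 1)
  alt <- substr(classes, 3, 3)
  bases <- c("A", "C", "G", "T")
  b5 <- sample(bases, n, replace = TRUE)
  b3 <- sample(bases, n, replace = TRUE)
  ctx <- paste0(b5, ref, b3)
  flip <- runif(n) < 0.5
  ref[flip] <- unname(DNA_COMP[substr(classes[flip], 1, 1)])
  alt[flip] <- unname(DNA_COMP[substr(classes[flip], 3, 3)])
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(ref = ref, alt = alt, context = ctx, class6 = classes)
}

default_genome <- function(n_chrom = 5, length_bp = 1e7) {
  setNames(rep(length_bp, n_chrom), paste0("chr", seq_len(n_chrom)))
}

#' Simulate a serial-tumor patient
#'
#' Places each clone's mutations on a miniature genome, then for every
#' timepoint draws site depth ~ Poisson(`depth_mean`) and alt reads ~
#' Binomial(depth, E[VAF]) with
#' `E[VAF] = purity * m * CCF / (purity * cn_t + (1 - purity) * 2)`.
#' Mutations with fewer than `call_min` alt reads at a timepoint are
#' omitted from that timepoint's call set (caller dropout); site depth is
#' still recorded in the per-timepoint coverage table so absences can be
#' classified as confident. Deterministic for a given seed.
#'
#' @param clones list of [clone_spec()] (default [default_clones()]).
#' @param depth_mean mean sequencing depth (default 200).
#' @param purity_by_timepoint tumor purity per timepoint (default 0.5 at
#'   each of three timepoints).
#' @param local_cn total tumor copy number at mutated loci (default 2).
#' @param multiplicity mutant-allele copies per tumor cell (default 1).
#' @param call_min minimum alt reads for a mutation to be called
#'   (default 3).
#' @param patient_id,subtype metadata labels.
#' @param genome named vector of chromosome lengths (default five 10-Mb
#'   chromosomes).
#' @param seed integer seed.
#' @param out_dir when non-`NULL`, VCF/SEG/coverage/metadata/truth files
#'   are written there.
#' @return list: `variants_by_timepoint`, `segments_by_timepoint`,
#'   `depths_by_timepoint`, `metas`, `truth` (with `$mutations` incl. the
#'   generating clone and true CCFs, and `$samples`), and `paths` when
#'   files were written.
#' @export
simulate_patient <- function(clones = default_clones(), depth_mean = 200,
                             purity_by_timepoint = c(0.5, 0.5, 0.5),
                             local_cn = 2, multiplicity = 1, call_min = 3,
                             patient_id = "P1", subtype = "primary_gbm",
                             genome = default_genome(), seed = 1,
                             out_dir = NULL) {
  stopifnot(length(clones) >= 1, depth_mean > 0)
  ntp <- length(purity_by_timepoint)
  withr::with_seed(seed, {
    n_total <- sum(vapply(clones, `[[`, numeric(1), "n_mutations"))
    chrom <- sample(names(genome), n_total, replace = TRUE)
    pos <- integer(n_total)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sample.int(genome[[ch]], length(idx))  # unique per chrom
    }
    muts <- NULL
    for (cl in clones) {
      if (cl$n_mutations == 0) next
      ids <- draw_snv_identities(cl$n_mutations, cl$spectrum_profile)
      coding <- runif(cl$n_mutations) < cl$coding_fraction
      effect <- ifelse(coding,
                       sample(c("missense", "synonymous", "nonsense", "splice"),
                              cl$n_mutations, replace = TRUE,
                              prob = c(0.6, 0.2, 0.1, 0.1)),
                       "noncoding")
      ccf_cols <- matrix(rep(cl$ccf_by_timepoint, each = cl$n_mutations),
                         cl$n_mutations, ntp,
                         dimnames = list(NULL, paste0("ccf_t", seq_len(ntp))))
      muts <- rbind(muts, data.frame(
        clone_id = cl$clone_id, ids, coding = coding, effect = effect,
        ccf_cols))
    }
    muts$chrom <- chrom[seq_len(nrow(muts))]
    muts$pos <- pos[seq_len(nrow(muts))]
    muts$gene <- sprintf("G%04d", seq_len(nrow(muts)))
    # plant an MMR hit in a hypermutated late clone
    hyper_clones <- vapply(clones, function(cl)
      cl$n_mutations >= 500 && cl$coding_fraction >= 0.99, logical(1))
    if (any(hyper_clones)) {
      i <- which(muts$clone_id == clones[[which(hyper_clones)[1]]]$clone_id)[1]
      muts$gene[i] <- "MSH6"; muts$effect[i] <- "missense"; muts$coding[i] <- TRUE
    }
    muts$multiplicity <- as.integer(multiplicity)
    muts$key <- variant_key(muts$chrom, muts$pos, muts$ref, muts$alt)

    sample_ids <- paste0(patient_id, "_T", seq_len(ntp))
    variants_by_tp <- segments_by_tp <- depths_by_tp <- vector("list", ntp)
    for (t in seq_len(ntp)) {
      p <- purity_by_timepoint[t]
      evaf <- p * muts$multiplicity * muts[[paste0("ccf_t", t)]] /
        (p * local_cn + (1 - p) * 2)
      if (any(evaf > 1)) stopf("invalid clone spec: expected VAF > 1 at timepoint %d", t)
      depth <- rpois(nrow(muts), depth_mean)
      alt <- rbinom(nrow(muts), depth, evaf)
      called <- alt >= call_min & depth > 0
      variants_by_tp[[t]] <- somatic_variants(data.frame(
        sample_id = rep(sample_ids[t], sum(called)),
        chrom = muts$chrom[called], pos = muts$pos[called],
        ref = muts$ref[called], alt = muts$alt[called],
        ref_count = depth[called] - alt[called], alt_count = alt[called],
        gene = muts$gene[called], effect = muts$effect[called],
        coding = muts$coding[called], context = muts$context[called]))
      segments_by_tp[[t]] <- validate_segments(data.frame(
        sample_id = sample_ids[t], chrom = names(genome),
        start = 1L, end = as.integer(genome),
        total_cn = local_cn, laf = 0.5))
      depths_by_tp[[t]] <- data.frame(chrom = muts$chrom, pos = muts$pos,
                                      depth = depth)
    }
    metas <- data.frame(sample_id = sample_ids, patient_id = patient_id,
                        timepoint = seq_len(ntp), purity = purity_by_timepoint,
                        subtype = subtype)
    truth_samples <- data.frame(
      sample_id = sample_ids, purity = purity_by_timepoint,
      hypermutator = vapply(seq_len(ntp), function(t) {
        any(vapply(clones[hyper_clones], function(cl)
          cl$ccf_by_timepoint[t] > 0, logical(1)))
      }, logical(1)))
    truth_mut <- muts[c("key", "clone_id", "chrom", "pos", "ref", "alt",
                        paste0("ccf_t", seq_len(ntp)), "multiplicity", "class6")]
    out <- list(variants_by_timepoint = variants_by_tp,
                segments_by_timepoint = segments_by_tp,
                depths_by_timepoint = depths_by_tp,
                metas = metas,
                truth = list(mutations = truth_mut, samples = truth_samples))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list()
      for (t in seq_len(ntp)) {
        paths$vcf[t] <- file.path(out_dir, sprintf("t%d.vcf", t))
        write_somatic_vcf(variants_by_tp[[t]], paths$vcf[t], sample_ids[t])
        paths$seg[t] <- file.path(out_dir, sprintf("t%d.seg", t))
        write_segments(segments_by_tp[[t]], paths$seg[t])
        paths$depth[t] <- file.path(out_dir, sprintf("t%d.depth.tsv", t))
        write.table(depths_by_tp[[t]], paths$depth[t], sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      paths$meta <- file.path(out_dir, "meta.tsv")
      write.table(metas, paths$meta, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$truth_mutations <- file.path(out_dir, "truth_mutations.tsv")
      write.table(truth_mut, paths$truth_mutations, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      paths$truth_samples <- file.path(out_dir, "truth_samples.tsv")
      write.table(truth_samples, paths$truth_samples, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

#' Simulate one chromosome's copy-number and breakpoint profile
#'
#' `amplifying`: copy states alternate between baseline 2 and one high
#' state of at least 20 copies, with an intra-chromosomal breakpoint of
#' support >= 110 at every segment junction and shifted lesser-allele
#' frequency on amplified segments. `deleting`: at least 30% of covered
#' length at CN <= 1, supported intra breaks, and (optionally) supported
#' inter-chromosomal links to a partner chromosome. `quiet`: a single
#' diploid segment with 0-2 low-support breakpoints.
#'
#' @param mode `"amplifying"`, `"deleting"` or `"quiet"`.
#' @param n_segments number of segments (default drawn uniformly 20-60;
#'   must be >= 2 for non-quiet modes).
#' @param chrom chromosome name, `chrom_length` its length in bp.
#' @param partner_chrom for `deleting`, add supported inter links to this
#'   chromosome (default none).
#' @param sample_id sample label.
#' @param seed integer seed.
#' @return list: `segments`, `breakpoints`, `truth` (one-row data.frame
#'   with `chrom`, `chromothriptic`, `event_type`).
#' @export
simulate_chromothripsis_chrom <- function(mode = c("quiet", "amplifying", "deleting"),
                                          n_segments = NULL, chrom = "chr1",
                                          chrom_length = 1e7,
                                          partner_chrom = NULL,
                                          sample_id = "S1", seed = 1) {
  mode <- match.arg(mode)
  withr::with_seed(seed, {
    if (mode == "quiet") {
      seg <- data.frame(sample_id = sample_id, chrom = chrom, start = 1L,
                        end = as.integer(chrom_length), total_cn = 2,
                        laf = round(runif(1, 0.42, 0.5), 3))
      nb <- sample(0:2, 1)
      bp <- if (nb) data.frame(
        sample_id = sample_id,
        chrom_a = chrom, pos_a = sort(sample.int(chrom_length, nb)),
        chrom_b = chrom, pos_b = sort(sample.int(chrom_length, nb)),
        support = sample(5:50, nb, replace = TRUE))
      else data.frame(sample_id = character(), chrom_a = character(),
                      pos_a = integer(), chrom_b = character(),
                      pos_b = integer(), support = integer())
      return(list(segments = validate_segments(seg),
                  breakpoints = canonical_breakpoints(bp),
                  truth = data.frame(chrom = chrom, chromothriptic = FALSE,
                                     event_type = "none")))
    }
    n_segments <- n_segments %||% sample(20:60, 1)
    stopifnot(n_segments >= 2)
    alt_state <- if (mode == "amplifying") sample(20:28, 1) else sample(0:1, 1)
    repeat {
      cuts <- sort(sample.int(chrom_length - 1, n_segments - 1))
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, as.integer(chrom_length))
      states <- rep(c(2, alt_state), length.out = n_segments)
      if (mode == "deleting") states <- rep(c(alt_state, 2), length.out = n_segments)
      len <- ends - starts + 1
      frac_alt <- sum(len[states == alt_state]) / sum(len)
      if (mode == "amplifying" || frac_alt >= 0.35) break
    }
    laf <- ifelse(states == 2, round(runif(n_segments, 0.4, 0.5), 3),
                  round(runif(n_segments, 0.0, 0.15), 3))
    seg <- data.frame(sample_id = sample_id, chrom = chrom, start = starts,
                      end = ends, total_cn = states, laf = laf)
    # one supported junction per adjacent segment pair
    bp <- data.frame(sample_id = sample_id,
                     chrom_a = chrom, pos_a = ends[-n_segments],
                     chrom_b = chrom, pos_b = starts[-1],
                     support = sample(110:300, n_segments - 1, replace = TRUE))
    if (mode == "deleting" && !is.null(partner_chrom)) {
      n_inter <- sample(2:4, 1)
      bp <- rbind(bp, data.frame(
        sample_id = sample_id,
        chrom_a = chrom, pos_a = sample(starts, n_inter),
        chrom_b = partner_chrom, pos_b = sample.int(chrom_length, n_inter),
        support = sample(110:300, n_inter, replace = TRUE)))
    }
    list(segments = validate_segments(seg),
         breakpoints = canonical_breakpoints(bp),
         truth = data.frame(chrom = chrom, chromothriptic = TRUE,
                            event_type = mode))
  })
}

#' Simulate SNVs from a 6-class substitution profile
#'
#' Classes are drawn i.i.d. from `profile`; flanking bases are uniform
#' over compatible trinucleotides and each variant is presented on a
#' random strand (pyrimidine or purine reference), so spectra must
#' strand-collapse to recover the profile.
#'
#' @param profile named 6-class probability vector (sums to 1).
#' @param n number of SNVs.
#' @param sample_id,chrom,chrom_length placement of the variants.
#' @param coding mark variants as coding missense (default TRUE).
#' @param depth simulated site depth (default 100; alt count is
#'   `depth/2`).
#' @param seed integer seed.
#' @return a [somatic_variants()] data.frame.
#' @export
simulate_spectrum <- function(profile, n, sample_id = "S1", chrom = "chr1",
                              chrom_length = 1e7, coding = TRUE, depth = 100,
                              seed = 1) {
  stopifnot(n >= 0, abs(sum(profile) - 1) < 1e-9)
  profile <- profile[SPECTRUM_CLASSES]
  withr::with_seed(seed, {
    if (n == 0)
      return(somatic_variants(data.frame(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), ref_count = integer(),
        alt_count = integer())))
    ids <- draw_snv_identities(n, profile)
    somatic_variants(data.frame(
      sample_id = sample_id, chrom = chrom,
      pos = sample.int(chrom_length, n),
      ref = ids$ref, alt = ids$alt,
      ref_count = depth - floor(depth / 2), alt_count = floor(depth / 2),
      gene = "", effect = if (coding) "missense" else "noncoding",
      coding = coding, context = ids$context))
  })
}

#' Simulate a labeled tumor cohort for the chromothripsis screen
#'
#' Per subtype, exactly `round(rate * n)` samples are planted positive
#' (drawn without replacement), so cohort-level recovery checks are exact
#' rather than binomial. Positive samples carry one chromothriptic
#' chromosome (amplifying or deleting at random) plus quiet chromosomes;
#' negative samples are entirely quiet.
#'
#' @param n_by_subtype named integer vector, e.g.
#'   `c(primary_gbm = 52, secondary_gbm = 57)`.
#' @param positive_rate_by_subtype named rates in `[0, 1]` parallel to
#'   `n_by_subtype`.
#' @param n_chrom_per_sample chromosomes simulated per sample (default 3).
#' @param seed integer seed.
#' @return list: `samples` (named list of `segments`/`breakpoints`),
#'   `metas`, `truth` (per-sample `chromothriptic` flag and event type).
#' @export
simulate_cohort <- function(n_by_subtype = c(primary_gbm = 52, secondary_gbm = 57),
                            positive_rate_by_subtype = c(primary_gbm = 16 / 52,
                                                         secondary_gbm = 1 / 57),
                            n_chrom_per_sample = 3, seed = 1) {
  stopifnot(all(positive_rate_by_subtype >= 0 & positive_rate_by_subtype <= 1),
            all(names(n_by_subtype) %in% names(positive_rate_by_subtype)))
  withr::with_seed(seed, {
    samples <- list(); metas <- NULL; truth <- NULL
    sub_seed <- 0L
    for (st in names(n_by_subtype)) {
      n <- n_by_subtype[[st]]
      np <- as.integer(round_half_away(positive_rate_by_subtype[[st]] * n))
      pos_idx <- if (np > 0) sample.int(n, np) else integer(0)
      for (i in seq_len(n)) {
        sid <- sprintf("%s_%03d", st, i)
        is_pos <- i %in% pos_idx
        mode_i <- if (is_pos) sample(c("amplifying", "deleting"), 1) else "quiet"
        segs <- NULL; bps <- NULL
        for (ch in seq_len(n_chrom_per_sample)) {
          sub_seed <- sub_seed + 1L
          mode_ch <- if (is_pos && ch == 1) mode_i else "quiet"
          sim <- simulate_chromothripsis_chrom(
            mode_ch, chrom = paste0("chr", ch), sample_id = sid,
            seed = (seed + 7919L * sub_seed) %% .Machine$integer.max)
          segs <- rbind(segs, sim$segments)
          bps <- rbind(bps, sim$breakpoints)
        }
        samples[[sid]] <- list(segments = segs,
                               breakpoints = canonical_breakpoints(bps))
        metas <- rbind(metas, data.frame(sample_id = sid, patient_id = sid,
                                         timepoint = 1L, purity = 0.5,
                                         subtype = st))
        truth <- rbind(truth, data.frame(sample_id = sid, subtype = st,
                                         chromothriptic = is_pos,
                                         event_type = mode_i))
      }
    }
    list(samples = samples, metas = metas, truth = truth)
  })
}
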