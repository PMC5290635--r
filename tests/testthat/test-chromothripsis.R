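test_that("chromosome features count switches, states and supported breaks", {
  seg1 <- make_segments("chr1", 1, 1000, 2)
  no_bp <- make_breakpoints(character(0), integer(0), character(0),
                            integer(0), integer(0))
  f <- chromosome_features(seg1, no_bp, "chr1")
  expect_equal(f$n_switches, 0L)
  expect_equal(f$n_intra_supported, 0L)
  expect_equal(f$n_segments, 1L)

  # states [2,20,2,20,2], 15 intra breakpoints of support 150
  seg <- make_segments("chr1", c(1, 101, 201, 301, 401),
                       c(100, 200, 300, 400, 500), c(2, 20, 2, 20, 2))
  bp <- make_breakpoints("chr1", seq(10, 150, by = 10), "chr1",
                         seq(450, 490, length.out = 15), rep(150L, 15))
  f <- chromosome_features(seg, bp, "chr1")
  expect_equal(f$n_switches, 4L)
  expect_equal(f$max_cn, 20)
  expect_equal(f$n_intra_supported, 15L)
  expect_equal(f$n_states, 2L)

  low <- bp; low$support <- 50L
  expect_equal(chromosome_features(seg, low, "chr1")$n_intra_supported, 0L)
  # features on a chromosome without segments
  expect_equal(chromosome_features(seg, bp, "chr9")$n_segments, 0L)
})

test_that("fractional copy numbers are rounded before oscillation counting", {
  seg <- make_segments("chr1", c(1, 101, 201), c(100, 200, 300),
                       c(2.1, 1.9, 2.4))
  f <- chromosome_features(seg, make_breakpoints(character(0), integer(0),
                                                 character(0), integer(0),
                                                 integer(0)), "chr1")
  expect_equal(f$n_switches, 0L)   # all round to state 2
})

test_that("deleted fraction and laf shift are length-weighted", {
  seg <- make_segments("chr1", c(1, 1001), c(1000, 1500), c(1, 2),
                       laf = c(0.1, 0.5))
  f <- chromosome_features(seg, make_breakpoints(character(0), integer(0),
                                                 character(0), integer(0),
                                                 integer(0)), "chr1")
  expect_equal(f$frac_deleted, 1000 / 1500)
  expect_equal(f$laf_shift, (0.4 * 1000 + 0 * 500) / 1500)
})

test_that("chromothripsis calls follow the amplifying/deleting gates", {
  # flat diploid genome: no calls
  quiet <- make_segments(paste0("chr", 1:3), 1, 1e6, 2)
  nobp <- make_breakpoints(character(0), integer(0), character(0),
                           integer(0), integer(0))
  expect_equal(call_chromothripsis(quiet, nobp), list())
  expect_equal(call_chromothripsis(quiet[0, ], nobp), list())

  # two oscillating high-copy chromosomes joined by supported inter links
  osc <- function(chrom) {
    n <- 12
    make_segments(chrom, seq(1, by = 100, length.out = n),
                  seq(100, by = 100, length.out = n),
                  rep(c(2, 22), 6))
  }
  seg <- rbind(osc("chr7"), osc("chr12"))
  intra <- function(chrom) make_breakpoints(chrom, seq(5, 1005, by = 100),
                                            chrom, seq(50, 1050, by = 100),
                                            rep(200L, 11))
  bp <- rbind(intra("chr7"), intra("chr12"),
              make_breakpoints("chr7", 150L, "chr12", 250L, 180L))
  calls <- call_chromothripsis(seg, bp)
  expect_length(calls, 1)
  expect_setequal(calls[[1]]$chroms, c("chr12", "chr7"))
  expect_equal(calls[[1]]$event_type, "amplifying")
  expect_gte(calls[[1]]$n_inter_links, 1)

  # without the inter link: two separate calls
  calls2 <- call_chromothripsis(seg, rbind(intra("chr7"), intra("chr12")))
  expect_length(calls2, 2)

  # deleting: 40% of length at CN <= 1, 12 switches, 11 supported breaks
  n <- 13
  states <- rep(c(1, 2), length.out = n)
  len <- ifelse(states == 1, 130, 100)
  ends <- cumsum(len); starts <- c(1, head(ends, -1) + 1)
  segd <- make_segments("chr3", starts, ends, states)
  bpd <- make_breakpoints("chr3", seq(5, 1205, by = 100)[1:11], "chr3",
                          seq(50, 1250, by = 100)[1:11], rep(150L, 11))
  callsd <- call_chromothripsis(segd, bpd)
  expect_length(callsd, 1)
  expect_equal(callsd[[1]]$event_type, "deleting")
  ff <- callsd[[1]]$features
  expect_gte(ff$frac_deleted, 0.3)
})

test_that("calls are invariant to row order and monotone in support_min", {
  sim <- simulate_chromothripsis_chrom("amplifying", seed = 44)
  shuffle <- withr::with_seed(1, {
    list(seg = sim$segments[sample(nrow(sim$segments)), ],
         bp = sim$breakpoints[sample(nrow(sim$breakpoints)), ])
  })
  c1 <- call_chromothripsis(sim$segments, sim$breakpoints)
  c2 <- call_chromothripsis(shuffle$seg, shuffle$bp)
  expect_equal(c1, c2)

  f_lo <- chromosome_features(sim$segments, sim$breakpoints, "chr1", 100)
  f_hi <- chromosome_features(sim$segments, sim$breakpoints, "chr1", 400)
  expect_lte(f_hi$n_intra_supported, f_lo$n_intra_supported)
  strict <- call_chromothripsis(sim$segments, sim$breakpoints,
                                params = ct_params(support_min = 10000))
  expect_lte(length(strict), length(c1))
})

test_that("double-minute candidates are connected high-copy components", {
  seg <- make_segments(c("chr7", "chr1", "chr2"), 1, 2e6, c(25, 22, 30))
  link <- make_breakpoints("chr7", 5e5, "chr1", 5e5, 150L)
  dm <- dm_candidates(seg, link)
  expect_length(dm, 1)                      # chr2's CN-30 segment has no edge
  expect_equal(dm[[1]]$chroms, c("chr1", "chr7"))
  expect_equal(nrow(dm[[1]]$segments), 2)
  expect_gte(nrow(dm[[1]]$linking_breakpoints), 1)

  # no incident breakpoints -> no component
  expect_length(dm_candidates(seg[3, ], link), 0)
  # all segments below amp_min -> empty
  low <- seg; low$total_cn <- 5
  expect_length(dm_candidates(low, link), 0)
  # unsupported link does not connect
  weak <- link; weak$support <- 10L
  expect_length(dm_candidates(seg, weak), 0)
  # breakpoint ends within merge_tol of a segment still connect
  near <- make_breakpoints("chr7", 2e6 + 5000, "chr1", 5e5, 150L)
  expect_length(dm_candidates(seg, near, merge_tol = 1e4), 1)
  expect_length(dm_candidates(seg, near, merge_tol = 100), 0)
})

test_that("DM components partition the qualifying segments", {
  sim <- simulate_chromothripsis_chrom("amplifying", seed = 77)
  dm <- dm_candidates(sim$segments, sim$breakpoints)
  seg_keys <- unlist(lapply(dm, function(cmp)
    paste(cmp$segments$chrom, cmp$segments$start)))
  expect_equal(anyDuplicated(seg_keys), 0L)
})

test_that("cohort summary counts positives per subtype", {
  metas <- data.frame(sample_id = c(paste0("P", 1:4), paste0("S", 1:3)),
                      subtype = rep(c("primary_gbm", "secondary_gbm"), c(4, 3)))
  calls <- setNames(c(list(list(1), list(), list(1), list()),
                      list(list(), list(), list(1))), metas$sample_id)
  summ <- summarize_cohort(calls, metas)
  expect_equal(summ$per_subtype$primary_gbm$n_positive, 2)
  expect_equal(summ$per_subtype$primary_gbm$percent_text, "50%")
  expect_equal(summ$per_subtype$secondary_gbm$fraction, 1 / 3)
  expect_error(summarize_cohort(calls, metas[-1, ]), "without metadata")

  hyper <- setNames(c(TRUE, rep(FALSE, 6)), metas$sample_id)
  s2 <- summarize_cohort(calls, metas, hyper_by_sample = hyper)
  expect_equal(s2$hypermutated$primary_gbm$n_positive, 1)
})
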