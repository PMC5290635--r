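test_that("multiplicity estimation matches the purity/ploidy model", {
  expect_equal(estimate_multiplicity(0.5, 1.0, 2, 2), 1L)   # diploid clonal het
  expect_equal(estimate_multiplicity(1.0, 1.0, 1, 2), 1L)   # LOH
  # 0.9 * (0.8*20 + 0.2*2) / 0.8 = 18.45 -> 18
  expect_equal(estimate_multiplicity(0.9, 0.8, 20, 2), 18L)
  expect_equal(estimate_multiplicity(0, 0.5, 2, 2), 1L)     # floor at 1
  expect_equal(estimate_multiplicity(1, 1, 20, 2), 20L)     # ceiling at round(cn)
  expect_error(estimate_multiplicity(0.5, 0, 2), "purity")
})

test_that("ccf computation: examples, cap and inconsistency flag", {
  expect_equal(ccf_from_vaf(0.5, 1, 2, 1)$ccf, 1.0)
  expect_equal(ccf_from_vaf(0.1, 0.4, 2, 1)$ccf, 0.5)   # 0.1*(0.8+1.2)/0.4
  expect_equal(ccf_from_vaf(0, 0.7, 3, 1)$ccf, 0)
  r <- ccf_from_vaf(0.9, 1, 2, 1)       # raw 1.8: capped and flagged
  expect_equal(r$ccf, 1.5)
  expect_equal(r$ccf_raw, 1.8)
  expect_true(r$flagged_inconsistent)
  expect_false(ccf_from_vaf(0.55, 1, 2, 1)$flagged_inconsistent)  # raw 1.1
  v <- make_variants(pos = 1L, ref_count = 0L, alt_count = 0L)
  expect_error(compute_ccf(v, data.frame(purity = 0.5), 2, 1), "depth")
})

test_that("ccf round-trips to vaf exactly when unclipped and is monotone in vaf", {
  grid <- expand.grid(vaf = c(0.05, 0.2, 0.4), purity = c(0.3, 0.5, 1),
                      cn = c(1, 2, 4), m = 1:2)
  grid <- grid[grid$m <= grid$cn, ]
  r <- ccf_from_vaf(grid$vaf, grid$purity, grid$cn, grid$m)
  unclipped <- !r$flagged_inconsistent & r$ccf_raw <= 1.5
  vaf_back <- grid$purity * grid$m * r$ccf /
    (grid$purity * grid$cn + (1 - grid$purity) * 2)
  expect_true(all(abs(vaf_back[unclipped] - grid$vaf[unclipped]) < 1e-12))

  vafs <- seq(0, 0.3, by = 0.01)
  ccfs <- ccf_from_vaf(vafs, 0.6, 3, 1)$ccf
  expect_true(all(diff(ccfs) >= 0))
  # purity 1, cn 2, m 1 limit: ccf = 2 vaf exactly
  expect_equal(ccf_from_vaf(vafs, 1, 2, 1)$ccf, 2 * vafs)
})

test_that("ccf matrix rows are the union of mutations with the absence mask rule", {
  seg <- make_segments("chr1", 1, 1e6, 2)
  mk <- function(pos, sid) make_variants(pos = pos, ref_count = 60L,
                                         alt_count = 40L, sample_id = sid)
  # timepoints carry {A,B}, {B,C}, {C} at positions 100, 200, 300
  v1 <- mk(c(100L, 200L), "T1"); v2 <- mk(c(200L, 300L), "T2"); v3 <- mk(300L, "T3")
  metas <- data.frame(sample_id = c("T1", "T2", "T3"), timepoint = 1:3,
                      purity = 1)
  depths <- replicate(3, data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                                    depth = 100L), simplify = FALSE)
  m <- assemble_ccf_matrix(list(v1, v2, v3), list(seg, seg, seg), metas,
                           depths_by_timepoint = depths)
  expect_equal(nrow(m$values), 3)                # union oracle
  expect_equal(unname(m$values[, 1]), c(0.8, 0.8, 0))  # vaf .4, purity 1 -> ccf .8
  a <- m$mask["chr1:100:C:T", ]
  expect_equal(unname(a), c("observed", "absent_confident", "absent_confident"))
  expect_true(all(m$values[m$mask == "absent_confident"] == 0))
  expect_true(all(clustering_rows(m)))

  # no depth table: absences cannot be confident, rows excluded from clustering
  m2 <- assemble_ccf_matrix(list(v1, v2, v3), list(seg, seg, seg), metas)
  expect_true(all(m2$mask[m2$mask != "observed"] == "absent_lowdepth"))
  expect_equal(sum(clustering_rows(m2)), 0)

  # low depth at an uncalled site excludes that row only
  depths[[2]]$depth <- c(5L, 100L, 100L)   # site 100 uncovered at timepoint 2
  m3 <- assemble_ccf_matrix(list(v1, v2, v3), list(seg, seg, seg), metas,
                            depths_by_timepoint = depths)
  expect_equal(unname(m3$mask["chr1:100:C:T", 2]), "absent_lowdepth")
  expect_false(clustering_rows(m3)[["chr1:100:C:T"]])
  expect_true(clustering_rows(m3)[["chr1:200:C:T"]])

  dup <- rbind(v1, v1[1, ])
  expect_error(assemble_ccf_matrix(list(dup, v2, v3), list(seg, seg, seg),
                                   metas), "duplicate variant key")
})

test_that("variants outside all segments error unless default_cn is given", {
  seg <- make_segments("chr1", 1, 150, 2)
  v <- make_variants(pos = c(100L, 500L), sample_id = "T1")
  metas <- data.frame(sample_id = c("T1", "T2"), timepoint = 1:2, purity = 1)
  expect_error(assemble_ccf_matrix(list(v, v[1, ]), list(seg, seg), metas),
               "not covered")
  m <- assemble_ccf_matrix(list(v, v[1, ]), list(seg, seg), metas,
                           default_cn = 2)
  expect_equal(unname(m$values[, 1]), c(0.8, 0.8))
})
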