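test_that("clone ploidy is the length-weighted mean total copy number", {
  tree <- make_tree("diploid>clone1")
  segs <- segment_table(data.frame(segment = c("a", "b"), chrom = "chr1",
                                   start = c(1, 1e6 + 1),
                                   end = c(1e6, 4e6)))   # 1 Mb and 3 Mb
  prof <- make_profile(tree, segs, A_tum = c(1, 2), B_tum = c(1, 2))
  p <- clone_ploidy(prof, segs)
  expect_equal(unname(p["clone1"]), (1e6 * 2 + 3e6 * 4) / 4e6)  # 3.5
  expect_equal(unname(p["diploid"]), 2)
  eq <- make_segments(2)
  prof2 <- make_profile(tree, eq, A_tum = c(1, 2), B_tum = c(1, 2))
  expect_equal(unname(clone_ploidy(prof2, eq)["clone1"]), 3)
})

test_that("WGD detection uses the parent ratio and the grandparent fallback", {
  tree <- make_tree("diploid>clone1 clone1>clone2 clone2>clone3")
  segs <- make_segments(4)
  tum <- tumour_clones(tree)
  A <- matrix(0, 4, 3, dimnames = list(segs$segment, tum))
  B <- A
  # totals: clone1 (5,4,4,4), clone2 = (5,5,5,5), clone3 = (10,6,6,6)
  A[, "clone1"] <- c(3, 2, 2, 2); B[, "clone1"] <- c(2, 2, 2, 2)
  A[, "clone2"] <- c(3, 3, 3, 3); B[, "clone2"] <- c(2, 2, 2, 2)
  A[, "clone3"] <- c(6, 4, 4, 4); B[, "clone3"] <- c(4, 2, 2, 2)
  prof <- clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
  flags <- detect_wgd(prof, tree, segs)
  expect_true(flags[["clone1"]])    # ratio to diploid root: 17/8 > 1.5
  # clone2/clone1 mean ratio = (1 + 1.25*3)/4 = 1.1875: not doubled
  expect_false(flags[["clone2"]])
  # clone3/clone2 = (2 + 1.2*3)/4 = 1.4 but clone3/clone1 = 1.625 with an
  # unflagged parent: grandparent rule fires
  expect_true(flags[["clone3"]])

  ident <- make_profile(tree, segs, A_tum = 1, B_tum = 1)
  expect_false(any(detect_wgd(ident, tree, segs)))
  doubled <- make_profile(tree, segs, A_tum = rep(c(2, 2, 2), each = 4),
                          B_tum = rep(c(2, 2, 2), each = 4))
  expect_true(detect_wgd(doubled, tree, segs)[["clone1"]])
})

test_that("segment event calls follow the gain/loss/LOH/amplification criteria", {
  tree <- make_tree("diploid>clone1 clone1>clone2")
  segs <- segment_table(data.frame(segment = c("a", "b"), chrom = "chr1",
                                   start = c(1, 1e6 + 1),
                                   end = c(1e6, 5e6)))    # 1 Mb and 4 Mb
  tum <- tumour_clones(tree)
  A <- matrix(c(2, 1,                       # clone1
                5, 1), 2, 2, dimnames = list(segs$segment, tum))
  B <- matrix(c(2, 1,
                2, 1), 2, 2, dimnames = list(segs$segment, tum))
  prof <- clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
  # clone2 ploidy = (1*7 + 4*2)/5 = 3
  ev <- call_segment_events(prof, tree, segs)
  amp_row <- ev[ev$child == "clone2" & ev$segment == "a", ]
  expect_true(amp_row$amplification)        # 5 > 4, 5 >= 4, 5 > ploidy 3
  expect_true(amp_row$gain)
  quiet <- ev[ev$child == "clone2" & ev$segment == "b", ]
  expect_false(any(quiet$gain, quiet$loss, quiet$loh, quiet$amplification))

  # LOH and loss on an edge (2,1) -> (2,0)
  A2 <- matrix(c(2, 2), 1, 2, dimnames = list("seg1", tum))
  B2 <- matrix(c(1, 0), 1, 2, dimnames = list("seg1", tum))
  prof2 <- clone_cn_profile(cbind(A2, diploid = 1), cbind(B2, diploid = 1))
  ev2 <- call_segment_events(prof2, tree, make_segments(1))
  r <- ev2[ev2$child == "clone2", ]
  expect_true(r$loh); expect_true(r$loss); expect_false(r$gain)
  # consistency: amplification implies gain, LOH implies loss
  for (e in list(ev, ev2)) {
    expect_true(all(!e$amplification | e$gain))
    expect_true(all(!e$loh | e$loss))
  }
})

test_that("arm-level events require 90% coverage and low parent LOH background", {
  tree <- make_tree("diploid>clone1 clone1>clone2")
  tum <- tumour_clones(tree)
  mk_arm <- function(lens, childA, parentA) {
    start <- cumsum(c(1, lens[-3]))
    segs <- segment_table(data.frame(segment = paste0("s", 1:3),
                                     chrom = "chr1", start = start,
                                     end = start + lens - 1, arm = "p"))
    A <- cbind(clone1 = parentA, clone2 = childA)
    rownames(A) <- segs$segment
    B <- matrix(1, 3, 2, dimnames = dimnames(A))
    prof <- clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
    ev <- call_segment_events(prof, tree, segs)
    call_arm_events(ev, prof, tree, segs)
  }
  # child at zero on 90% of the arm, parent on 15%: arm LOH
  out <- mk_arm(c(75, 15, 10), childA = c(0, 0, 1), parentA = c(1, 0, 1))
  expect_true(out$loh[out$child == "clone2"])
  # parent zero background 25%: no arm LOH
  out2 <- mk_arm(c(70, 25, 5), childA = c(0, 0, 1), parentA = c(1, 0, 1))
  expect_false(out2$loh[out2$child == "clone2"])

  # whole-arm single-segment loss vs 85% loss
  segs1 <- segment_table(data.frame(segment = "s1", chrom = "chr1", start = 1,
                                    end = 100, arm = "p"))
  A1 <- matrix(c(1, 0), 1, 2, dimnames = list("s1", tum))
  B1 <- matrix(1, 1, 2, dimnames = list("s1", tum))
  prof1 <- clone_cn_profile(cbind(A1, diploid = 1), cbind(B1, diploid = 1))
  ev1 <- call_segment_events(prof1, tree, segs1)
  out1 <- call_arm_events(ev1, prof1, tree, segs1)
  expect_true(out1$loss[out1$child == "clone2"])
  out3 <- mk_arm(c(85, 10, 5), childA = c(0, 1, 1), parentA = c(1, 1, 1))
  expect_false(out3$loss[out3$child == "clone2"])
})

test_that("sample-level arm LOH needs 98% of the arm below half a copy", {
  segs <- segment_table(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 99),
    end = c(98, 100), arm = "p"))                       # 98% / 2% by length
  mk_fr <- function(fA) fractional_cn(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 99),
    end = c(98, 100), sample = "S1",
    fA = fA, fA_lo = pmax(fA - 0.1, 0), fA_hi = fA + 0.1,
    fB = c(1, 1), fB_lo = c(0.9, 0.9), fB_hi = c(1.1, 1.1)))
  expect_true(sample_level_arm_loh(mk_fr(c(0.2, 0.2)), segs)$loh)
  expect_true(sample_level_arm_loh(mk_fr(c(0.2, 0.6)), segs)$loh)   # 98%
  segs97 <- segment_table(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 98),
    end = c(97, 100), arm = "p"))                       # 97% / 3%
  fr97 <- fractional_cn(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 98),
    end = c(97, 100), sample = "S1",
    fA = c(0.2, 0.6), fA_lo = c(0.1, 0.5), fA_hi = c(0.3, 0.7),
    fB = c(1, 1), fB_lo = c(0.9, 0.9), fB_hi = c(1.1, 1.1)))
  expect_false(sample_level_arm_loh(fr97, segs97)$loh)
  # alleles may not be combined: A low on 60%, B low on the disjoint 40%
  segsAB <- segment_table(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 61),
    end = c(60, 100), arm = "p"))
  frAB <- fractional_cn(data.frame(
    segment = paste0("s", 1:2), chrom = "chr1", start = c(1, 61),
    end = c(60, 100), sample = "S1",
    fA = c(0.2, 1.0), fA_lo = c(0.1, 0.9), fA_hi = c(0.3, 1.1),
    fB = c(1.0, 0.2), fB_lo = c(0.9, 0.1), fB_hi = c(1.1, 0.3)))
  expect_false(sample_level_arm_loh(frAB, segsAB)$loh)
})

test_that("per-edge SCNA counts merge runs of identical deltas", {
  tree <- make_tree("diploid>clone1")
  segs <- make_segments(4)
  prof <- make_profile(tree, segs, A_tum = c(2, 2, 1, 2), B_tum = 1)
  # deltas +1,+1,0,+1 on one chromosome: two gains
  out <- count_scnas_per_edge(prof, tree, segs)
  expect_equal(out$n_gains, 2)
  expect_equal(out$n_scnas, 2)

  prof2 <- make_profile(tree, make_segments(2), A_tum = c(3, 2), B_tum = 1)
  out2 <- count_scnas_per_edge(prof2, tree, make_segments(2))
  expect_equal(out2$n_gains, 2)      # amplitudes +2 and +1 break the run

  prof3 <- make_profile(tree, make_segments(2), A_tum = c(2, 0), B_tum = 1)
  out3 <- count_scnas_per_edge(prof3, tree, make_segments(2))
  expect_equal(out3$n_gains, 1)
  expect_equal(out3$n_losses, 1)
  expect_equal(out3$n_scnas, 2)
})

test_that("SCNA run counts agree with a naive scanner on random profiles", {
  set.seed(33)
  for (rep in 1:10) {
    cfg <- sim_config(n_clones = 6, n_samples = 2, n_segments = 25,
                      seed = 100 + rep)
    tp <- simulate_tree_and_profile(cfg)
    out <- count_scnas_per_edge(tp$profile, tp$tree, tp$segments)
    for (i in seq_len(nrow(out))) {
      cl <- out$child[i]; pa <- out$parent[i]
      ref <- c(gains = 0L, losses = 0L)
      tot_delta <- 0
      for (al in c("A", "B")) {
        d <- tp$profile[[al]][tp$segments$segment, cl] -
          tp$profile[[al]][tp$segments$segment, pa]
        ref <- ref + oracle_count_runs(d, tp$segments$chrom)
        tot_delta <- tot_delta + sum(abs(d))
      }
      expect_equal(out$n_gains[i], unname(ref["gains"]))
      expect_equal(out$n_losses[i], unname(ref["losses"]))
      expect_lte(out$n_scnas[i], tot_delta)  # runs merge, never split
    }
  }
})

test_that("clone classification identifies shared, seeding and specific clones", {
  tree <- make_tree("diploid>clone1 clone1>clone2 clone2>clone3 clone1>clone4")
  sites <- c(P1 = "primary", M1 = "metastasis")
  # clone3 (leaf) only in metastasis, its parent clone2 in both
  u <- make_proportions(tree, matrix(c(
    0.5, 0.2, 0.0, 0.2,      # P1
    0.1, 0.3, 0.4, 0.0), 4,  # M1
    dimnames = list(paste0("clone", 1:4), c("P1", "M1"))))
  out <- classify_clones(tree, u, sites)
  expect_equal(out$class[out$clone == "clone2"], "seeding")
  expect_true(out$is_shared[out$clone == "clone2"])
  expect_equal(out$class[out$clone == "clone3"], "metastasis_specific")
  expect_equal(out$class[out$clone == "clone4"], "primary_specific")
  expect_equal(out$class[out$clone == "clone1"], "MRCA")
  expect_false(out$is_seeding[out$clone == "clone1"])  # clone2 is more recent

  # truncal-only sharing: the MRCA is the seeding clone
  u2 <- make_proportions(tree, matrix(c(
    0.5, 0.3, 0.0, 0.1,
    0.6, 0.0, 0.0, 0.0), 4,
    dimnames = list(paste0("clone", 1:4), c("P1", "M1"))))
  out2 <- classify_clones(tree, u2, sites)
  expect_true(out2$is_seeding[out2$clone == "clone1"])

  # two independent shared branches: polyclonal seeding
  u3 <- make_proportions(tree, matrix(c(
    0.2, 0.2, 0.2, 0.2,
    0.0, 0.2, 0.2, 0.3), 4,
    dimnames = list(paste0("clone", 1:4), c("P1", "M1"))))
  out3 <- classify_clones(tree, u3, sites)
  expect_equal(sort(out3$clone[out3$is_seeding]), c("clone3", "clone4"))

  # no metastatic samples: everything primary-specific except the MRCA
  out4 <- classify_clones(tree, u, c(P1 = "primary", M1 = "primary"))
  expect_false(any(out4$is_shared))
  expect_true(all(out4$class[!out4$is_mrca] == "primary_specific"))
})

test_that("CCD is the maximum pairwise distance of concatenated profiles", {
  tree <- make_tree("diploid>clone1 clone1>clone2 clone1>clone3")
  segs <- make_segments(4)
  A <- matrix(1, 4, 3, dimnames = list(segs$segment, tumour_clones(tree)))
  B <- A
  prof_same <- clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
  expect_equal(compute_ccd(prof_same), 0)

  # clone2 differs from clone1 by one copy in exactly 4 segment-alleles
  A2 <- A; A2[1:2, "clone2"] <- 2
  B2 <- B; B2[3:4, "clone2"] <- 2
  prof <- clone_cn_profile(cbind(A2, diploid = 1), cbind(B2, diploid = 1))
  expect_equal(compute_ccd(prof, clones = c("clone1", "clone2")), 2)

  # three clones: equals the brute-force pairwise maximum
  A3 <- A2; A3[, "clone3"] <- c(3, 1, 1, 1)
  prof3 <- clone_cn_profile(cbind(A3, diploid = 1), cbind(B2, diploid = 1))
  cls <- tumour_clones(tree)
  vec <- function(cl) c(prof3$A[, cl], prof3$B[, cl])
  ref <- max(apply(combn(cls, 2), 2,
                   function(p) sqrt(sum((vec(p[1]) - vec(p[2]))^2))))
  expect_equal(compute_ccd(prof3), ref)
  # adding clones never decreases the score
  expect_gte(compute_ccd(prof3), compute_ccd(prof3, clones = cls[1:2]))
  expect_equal(compute_ccd(prof3, clones = "clone1"), 0)

  # lymph-only clones are dropped by the helper
  u <- make_proportions(tree, matrix(c(0.4, 0.3, 0.0,
                                       0.2, 0.0, 0.5), 3, 2,
                                     dimnames = list(cls, c("P1", "L1"))))
  keep <- drop_lymph_only(u, c(P1 = "primary", L1 = "lymph_node"))
  expect_equal(sort(keep), c("clone1", "clone2"))
})
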