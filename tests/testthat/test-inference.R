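test_that("single-clone segments deconvolve exactly", {
  tree <- make_tree("diploid>clone1")
  segments <- make_segments(1)
  u <- make_proportions(tree, matrix(1, 1, 1, dimnames = list("clone1", "S1")))
  fr <- fractional_cn(data.frame(
    segment = "seg1", chrom = "chr1", start = 1, end = 1e6, sample = "S1",
    fA = 3, fA_lo = 2.9, fA_hi = 3.1, fB = 1, fB_lo = 0.9, fB_hi = 1.1))
  sol <- solve_segment(tree, u, fr, segments, "seg1", lambda = 3)
  expect_equal(unname(sol$cA), 3)
  expect_equal(unname(sol$cB), 1)
  expect_equal(sol$obj1, 0)
  expect_lt(sol$obj2, 1e-9)
})

test_that("a zero event budget forces the diploid labelling", {
  tree <- make_tree("diploid>clone1 clone1>clone2")
  segments <- make_segments(1)
  u <- make_proportions(tree, matrix(c(0.5, 0.4), 2, 1,
                                     dimnames = list(c("clone1", "clone2"),
                                                     "S1")))
  fr <- fractional_cn(data.frame(
    segment = "seg1", chrom = "chr1", start = 1, end = 1e6, sample = "S1",
    fA = 1.8, fA_lo = 1.7, fA_hi = 1.9, fB = 0.9, fB_lo = 0.8, fB_hi = 1.0))
  sol <- solve_segment(tree, u, fr, segments, "seg1", lambda = 0)
  expect_equal(unname(sol$cA), c(1, 1))
  expect_equal(unname(sol$cB), c(1, 1))
  # diploid prediction is 0.9 for both alleles: A misses [1.7, 1.9]
  expect_equal(sol$obj1, 1)
  expect_equal(sol$events, 0)
})

test_that("noise-free chain recovery matches the brute-force optimum", {
  set.seed(101)
  tree <- make_tree("diploid>clone1 clone1>clone2 clone2>clone3")
  segments <- make_segments(1)
  u <- make_proportions(tree, matrix(c(0.3, 0.3, 0.3,
                                       0.1, 0.2, 0.6), 3, 2,
                                     dimnames = list(paste0("clone", 1:3),
                                                     c("S1", "S2"))))
  prof <- make_profile(tree, segments, A_tum = c(2, 3, 3), B_tum = c(1, 1, 0))
  fr <- fractional_from_profile(prof, u, segments)
  true_ev <- profile_events(prof, tree)
  sol <- solve_segment(tree, u, fr, segments, "seg1", lambda = true_ev)
  tum <- tumour_clones(tree)
  expect_equal(sol$cA[tum], setNames(prof$A["seg1", tum], tum))
  expect_equal(sol$cB[tum], setNames(prof$B["seg1", tum], tum))
  fm <- clonecn:::fractional_matrices(fr, segments, colnames(u))
  orc <- oracle_solve(tree, u, fm$fA["seg1", ], fm$loA["seg1", ],
                      fm$hiA["seg1", ], fm$fB["seg1", ], fm$loB["seg1", ],
                      fm$hiB["seg1", ], cmax = 4, lambda = true_ev)
  expect_equal(orc$n_optima, 1L)           # identifiable fixture
  expect_equal(unname(sol$cA), unname(orc$cA))
  expect_equal(unname(sol$cB), unname(orc$cB))
})

test_that("solver matches exhaustive enumeration on random small instances", {
  set.seed(2024)
  opts <- solver_options(cmax = 4, time_limit = 60)
  for (rep in 1:25) {
    inst <- random_instance(sample(2:4, 1), sample(1:2, 1))
    lam <- sample(0:6, 1)
    segments <- make_segments(1)
    fr <- fractional_cn(data.frame(
      segment = "seg1", chrom = "chr1", start = 1, end = 1e6,
      sample = colnames(inst$u),
      fA = inst$fA, fA_lo = inst$loA, fA_hi = inst$hiA,
      fB = inst$fB, fB_lo = inst$loB, fB_hi = inst$hiB))
    elig <- matrix(inst$elig, 1, dimnames = list("seg1", names(inst$elig)))
    sol <- solve_segment(inst$tree, inst$u, fr, segments, "seg1", lam,
                         eligibility = elig, options = opts)
    orc <- oracle_solve(inst$tree, inst$u, inst$fA, inst$loA, inst$hiA,
                        inst$fB, inst$loB, inst$hiB, elig = inst$elig,
                        cmax = 4, lambda = lam)
    expect_equal(sol$obj1, orc$obj1, info = paste("rep", rep))
    expect_equal(sol$obj2, orc$obj2, tolerance = 1e-9,
                 info = paste("rep", rep))
    expect_equal(sol$events, orc$events, info = paste("rep", rep))
  }
})

test_that("budget sweeps are monotone and stop after the configured patience", {
  tree <- make_tree("diploid>clone1 clone1>clone2")
  segments <- make_segments(1)
  u <- make_proportions(tree, matrix(c(0.5, 0.3), 2, 1,
                                     dimnames = list(c("clone1", "clone2"),
                                                     "S1")))
  # optimum leaves a fit residual, so the tail of the curve is flat
  fr <- fractional_cn(data.frame(
    segment = "seg1", chrom = "chr1", start = 1, end = 1e6, sample = "S1",
    fA = 2.15, fA_lo = 2.05, fA_hi = 2.25, fB = 0.8, fB_lo = 0.7,
    fB_hi = 0.9))
  opt <- solver_options(patience = 2)
  sw <- sweep_lambda(tree, u, fr, segments, "seg1", options = opt)
  cv <- sw$curve
  expect_true(all(diff(cv$obj1) <= 0))
  expect_true(all(diff(cv$obj2) <= 1e-9))
  # the sweep retains exactly `patience` stalled budgets after the last
  # meaningful improvement
  delta <- 0.25 * 0.2
  meaningful <- c(TRUE, diff(cv$obj1) < 0 | -diff(cv$obj2) > delta)
  expect_equal(nrow(cv) - max(which(meaningful)), 2)
})

test_that("model selection finds the knee and falls back to parsimony", {
  # hand-checked Kneedle knee
  curve <- data.frame(lambda = 0:3, obj1 = 0, obj2 = c(10, 2, 1.9, 1.9))
  expect_equal(select_lambda(curve), 1)
  # constant curve: minimal budget
  flat <- data.frame(lambda = 0:3, obj1 = 0, obj2 = rep(1, 4))
  expect_equal(select_lambda(flat), 0)
  # strictly linear curve: smallest budget within tolerance of the minimum
  lin <- data.frame(lambda = 0:5, obj1 = 0, obj2 = 10 - (0:5))
  expect_equal(select_lambda(lin), 5)
  # objective-1 filter dominates the knee
  o1 <- data.frame(lambda = 0:3, obj1 = c(2, 1, 0, 0), obj2 = c(10, 2, 1.9, 1.9))
  expect_equal(select_lambda(o1), 2)
  # noise floor walks an insignificant knee back to the feasible budget
  noisy <- data.frame(lambda = 0:3, obj1 = 0, obj2 = c(0.15, 0.13, 0.12, 0.115))
  expect_equal(select_lambda(noisy, min_improvement = 0.05), 0)
})

test_that("tumour-level inference is segment-independent and order-invariant", {
  set.seed(5)
  cfg <- sim_config(n_clones = 5, n_samples = 3, n_segments = 8, seed = 5)
  sim <- simulate_tumour(cfg)
  fit <- infer_tumour(sim$tree, sim$proportions, sim$fractional, sim$segments)
  # single-segment runs agree with the joint run
  for (seg in sim$segments$segment[c(1, 4)]) {
    sub_segments <- sim$segments[sim$segments$segment == seg, ]
    class(sub_segments) <- c("segment_table", "data.frame")
    sub_fr <- sim$fractional[sim$fractional$segment == seg, ]
    one <- infer_tumour(sim$tree, sim$proportions, sub_fr, sub_segments)
    expect_equal(one$profile$A[seg, ], fit$profile$A[seg, ])
    expect_equal(one$profile$B[seg, ], fit$profile$B[seg, ])
  }
  # permuting the fractional table rows changes nothing
  perm <- sim$fractional[sample(nrow(sim$fractional)), ]
  fit2 <- infer_tumour(sim$tree, sim$proportions, perm, sim$segments)
  expect_equal(fit2$profile$A, fit$profile$A)
  expect_equal(fit2$profile$B, fit$profile$B)
})

test_that("noise-free tumours are recovered exactly on identifiable segments", {
  set.seed(77)
  # 6 clones, 3 samples, 12 segments, copy numbers capped at 2 so the
  # brute-force oracle can certify identifiability per segment
  cfg <- sim_config(n_clones = 6, n_samples = 3, n_segments = 12,
                    cmax_true = 2, sparsity = 0.15, seed = 77)
  tp <- simulate_tree_and_profile(cfg)
  u <- simulate_proportions(tp$tree, cfg)
  fr <- fractional_from_profile(tp$profile, u, tp$segments, half = 0.1)
  fit <- infer_tumour(tp$tree, u, fr, tp$segments,
                      options = solver_options(cmax = 2, min_improvement = 0))
  fm <- clonecn:::fractional_matrices(fr, tp$segments, colnames(u))
  tum <- tumour_clones(tp$tree)
  n_ident <- 0
  for (seg in tp$segments$segment) {
    orc <- oracle_solve(tp$tree, u, fm$fA[seg, ], fm$loA[seg, ],
                        fm$hiA[seg, ], fm$fB[seg, ], fm$loB[seg, ],
                        fm$hiB[seg, ], cmax = 2, lambda = Inf)
    if (orc$n_optima == 1L) {
      n_ident <- n_ident + 1
      expect_equal(fit$profile$A[seg, tum], tp$profile$A[seg, tum],
                   info = seg)
      expect_equal(fit$profile$B[seg, tum], tp$profile$B[seg, tum],
                   info = seg)
      expect_equal(unname(fit$profile$A[seg, tum]), unname(orc$cA[tum]),
                   info = seg)
    }
  }
  expect_gt(n_ident, 0)
})
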