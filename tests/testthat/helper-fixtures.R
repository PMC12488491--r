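# small programmatic fixtures shared across tests

# linear or branching toy tree from a parent->child string like
# "diploid>clone1 clone1>clone2"
make_tree <- function(spec) {
  pairs <- strsplit(strsplit(spec, " ")[[1]], ">")
  clone_tree(data.frame(parent = vapply(pairs, `[`, "", 1),
                        child = vapply(pairs, `[`, "", 2)))
}

make_segments <- function(m, len = 1e6, chrom = "chr1", arm = NULL) {
  start <- cumsum(c(1, rep(len, m - 1)))
  df <- data.frame(segment = paste0("seg", seq_len(m)), chrom = chrom,
                   start = start, end = start + len - 1)
  if (!is.null(arm)) df$arm <- arm
  segment_table(df)
}

make_proportions <- function(tree, u_tumour) {
  # u_tumour: tumour-clone x sample matrix; diploid absorbs the rest
  u <- rbind(diploid = 1 - colSums(u_tumour), u_tumour)
  clone_proportions(u, tree = tree)
}

make_profile <- function(tree, segments, A_tum, B_tum) {
  tum <- tumour_clones(tree)
  A <- matrix(A_tum, nrow(segments), length(tum),
              dimnames = list(segments$segment, tum))
  B <- matrix(B_tum, nrow(segments), length(tum),
              dimnames = list(segments$segment, tum))
  clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
}

# exact (noise-free) fractional table from a profile, bounds +/- half
fractional_from_profile <- function(profile, proportions, segments,
                                    half = 0.1) {
  mix <- mixture_fractional(profile, proportions)
  rows <- lapply(colnames(mix$A), function(r)
    data.frame(segment = segments$segment, chrom = segments$chrom,
               start = segments$start, end = segments$end, sample = r,
               fA = mix$A[, r], fA_lo = pmax(mix$A[, r] - half, 0),
               fA_hi = mix$A[, r] + half,
               fB = mix$B[, r], fB_lo = pmax(mix$B[, r] - half, 0),
               fB_hi = mix$B[, r] + half, stringsAsFactors = FALSE))
  fractional_cn(do.call(rbind, rows), segments = segments)
}

# total events over all edges and alleles of a profile
profile_events <- function(profile, tree) {
  ev <- 0
  for (al in c("A", "B")) for (cl in tumour_clones(tree)) {
    pa <- tree$parent[[cl]]
    ev <- ev + sum(abs(profile[[al]][, cl] - profile[[al]][, pa]))
  }
  ev
}

# random small instance for oracle-equivalence checks
random_instance <- function(n_clones, n_samples, cmax = 4) {
  clones <- paste0("clone", seq_len(n_clones))
  parent <- c("diploid", if (n_clones > 1)
    clones[sapply(2:n_clones, function(i) sample.int(i - 1, 1))])
  tree <- clone_tree(data.frame(parent = parent, child = clones))
  u_t <- matrix(stats::runif(n_clones * n_samples, 0, 1), n_clones,
                dimnames = list(clones, paste0("S", seq_len(n_samples))))
  purity <- stats::runif(n_samples, 0.3, 0.9)
  u_t <- sweep(u_t, 2, colSums(u_t), "/")
  u_t <- sweep(u_t, 2, purity, "*")
  u <- make_proportions(tree, u_t)
  k <- n_samples
  fA <- stats::runif(k, 0, 3); fB <- stats::runif(k, 0, 2)
  half <- stats::runif(k, 0.05, 0.3)
  elig <- setNames(sample(c(TRUE, FALSE), n_clones, replace = TRUE), clones)
  list(tree = tree, u = u, fA = fA, loA = pmax(fA - half, 0), hiA = fA + half,
       fB = fB, loB = pmax(fB - half, 0), hiB = fB + half,
       elig = elig, cmax = cmax)
}
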