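#' Simulation configuration
#'
#' Defaults emulate a multi-region whole-exome study of an SCNA-rich tumour:
#' a handful of bulk samples per tumour, a genome of ~100 copy-number
#' segments, coverage parameter 1000, a moderate chance of truncal
#' whole-genome doubling, and denser truncal than subclonal copy-number
#' change.
#'
#' @param n_clones number of tumour clones (MRCA included).
#' @param n_samples number of bulk samples.
#' @param n_segments number of genomic segments.
#' @param n_chromosomes chromosomes the segments are spread over
#'   (`NULL`: `min(22, max(1, round(n_segments / 5)))`).
#' @param coverage expected coverage parameter \eqn{\gamma} per sample
#'   (Poisson read-depth mean scale and binomial BAF trial count).
#' @param purity_range per-sample tumour purity drawn uniformly from this
#'   interval.
#' @param dirichlet_alpha symmetric Dirichlet concentration for mixing the
#'   clones present in a sample.
#' @param sparsity probability that a clone (other than the MRCA) is absent
#'   from a given sample; 0 makes every clone present everywhere.
#' @param wgd_prob probability of a whole-genome doubling on the truncal edge.
#' @param truncal_events,subclonal_events Poisson means of the number of
#'   interval SCNA events on the truncal edge and on each subclonal edge.
#' @param run_mean mean number of contiguous segments spanned by one event.
#' @param gain_prob probability that an event is a gain rather than a loss.
#' @param cmax_true per-allele cap on generated copy numbers.
#' @param max_runs sign-run bound respected by construction (as in the
#'   solver's evolutionary model).
#' @param noise_sd standard deviation used to build the interval bounds
#'   around each observed fractional copy number.
#' @param z half-width of the bounds in units of `noise_sd` (default 1.96).
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 8L, n_samples = 3L, n_segments = 100L,
                       n_chromosomes = NULL, coverage = 1000,
                       purity_range = c(0.4, 0.9), dirichlet_alpha = 1,
                       sparsity = 0.25, wgd_prob = 0.3,
                       truncal_events = 6, subclonal_events = 2,
                       run_mean = 3, gain_prob = 0.55, cmax_true = 8L,
                       max_runs = 2L, noise_sd = 0.1, z = 1.96, seed = NULL) {
  if (is.null(n_chromosomes))
    n_chromosomes <- min(22L, max(1L, round(n_segments / 5)))
  stopifnot(n_clones >= 1, n_samples >= 1, n_segments >= 1, coverage >= 1,
            all(purity_range > 0), all(purity_range <= 1),
            sparsity >= 0, sparsity <= 1, wgd_prob >= 0, wgd_prob <= 1,
            gain_prob >= 0, gain_prob <= 1, run_mean >= 1, noise_sd > 0)
  structure(as.list(environment()), class = "sim_config")
}

maybe_seed <- function(config) if (!is.null(config$seed)) set.seed(config$seed)

#' Simulate a clone tree with a ground-truth copy-number profile
#'
#' Builds a random rooted tree (diploid root, MRCA, random attachment of the
#' remaining clones), then walks it in preorder placing interval SCNA events:
#' each event shifts one allele by one copy over a contiguous run of segments
#' on one chromosome; an optional whole-genome doubling doubles both alleles
#' on the truncal edge. LOH persistence, the sign-run (alternation) bound and
#' the homozygous-deletion length rule hold by construction.
#'
#' @param config a [sim_config()]
#' @return list with `tree`, `segments`, `profile` (a `clone_cn_profile`).
#' @export
simulate_tree_and_profile <- function(config) {
  maybe_seed(config)
  n <- config$n_clones; m <- config$n_segments
  clones <- paste0("clone", seq_len(n))
  parent <- c("diploid", if (n > 1)
    clones[sapply(2:n, function(i) sample.int(i - 1L, 1L))])
  tree <- clone_tree(data.frame(parent = parent, child = clones))

  ## segment layout
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), m))
  len <- round(stats::rlnorm(m, log(5e6), 0.8))
  segs <- do.call(rbind, lapply(split(seq_len(m), chrom_of), function(i) {
    start <- cumsum(c(1, len[i][-length(i)]))
    data.frame(segment = paste0("seg", sprintf("%03d", i)),
               chrom = paste0("chr", chrom_of[i][1]),
               start = start, end = start + len[i] - 1,
               stringsAsFactors = FALSE)
  }))
  tot <- tapply(segs$end, segs$chrom, max)
  mid <- (segs$start + segs$end) / 2
  segs$arm <- ifelse(mid <= tot[segs$chrom] / 2, "p", "q")
  segments <- segment_table(segs)
  m_ord <- segments$segment

  tum <- tumour_clones(tree)
  A <- matrix(1, m, n, dimnames = list(m_ord, tum))
  B <- A
  runsA <- matrix(0L, m, n, dimnames = dimnames(A)); runsB <- runsA
  signA <- runsA; signB <- runsA
  chrom_idx <- split(seq_len(m), segments$chrom)

  wgd <- stats::runif(1) < config$wgd_prob
  for (cl in tum) {
    pa <- tree$parent[[cl]]
    if (pa != "diploid") {
      A[, cl] <- A[, pa]; B[, cl] <- B[, pa]
      runsA[, cl] <- runsA[, pa]; signA[, cl] <- signA[, pa]
      runsB[, cl] <- runsB[, pa]; signB[, cl] <- signB[, pa]
    }
    truncal <- pa == "diploid"
    if (truncal && wgd) {
      for (al in c("A", "B")) {
        M <- get(al); rs <- get(paste0("runs", al)); sg <- get(paste0("sign", al))
        nz <- M[, cl] > 0
        rs[nz, cl] <- rs[nz, cl] + (sg[nz, cl] != 1L)
        sg[nz, cl] <- 1L
        M[, cl] <- 2 * M[, cl]
        assign(al, M); assign(paste0("runs", al), rs); assign(paste0("sign", al), sg)
      }
    }
    n_ev <- stats::rpois(1, if (truncal) config$truncal_events else
      config$subclonal_events)
    for (e in seq_len(n_ev)) {
      al <- sample(c("A", "B"), 1L)
      delta <- if (stats::runif(1) < config$gain_prob) 1L else -1L
      ci <- chrom_idx[[sample(length(chrom_idx), 1L,
                              prob = lengths(chrom_idx))]]
      first <- sample(length(ci), 1L)
      span <- 1L + stats::rpois(1, config$run_mean - 1)
      targets <- ci[first:min(length(ci), first + span - 1L)]
      M <- get(al); other <- get(if (al == "A") "B" else "A")
      rs <- get(paste0("runs", al)); sg <- get(paste0("sign", al))
      for (s in targets) {
        v <- M[s, cl] + delta
        if (v < 0 || v > config$cmax_true) next
        if (M[s, cl] == 0) next                       # LOH is irreversible
        if (v == 0 && other[s, cl] == 0 &&
            segments$length[s] >= 5e7) next           # no long homdels
        nr <- rs[s, cl] + (sg[s, cl] != delta)
        if (nr > config$max_runs) next                # alternation bound
        M[s, cl] <- v; rs[s, cl] <- nr; sg[s, cl] <- delta
      }
      assign(al, M); assign(paste0("runs", al), rs); assign(paste0("sign", al), sg)
    }
  }
  profile <- clone_cn_profile(cbind(A, diploid = 1), cbind(B, diploid = 1))
  list(tree = tree, segments = segments, profile = profile, wgd = wgd)
}

#' Simulate clone proportions across samples
#'
#' Each sample holds a lineage-biased subset of clones (the MRCA always; any
#' other clone is retained with probability `1 - sparsity` when its parent is
#' present and half that otherwise). Present clones receive symmetric
#' Dirichlet weights scaled by the sample purity; the diploid clone takes the
#' rest. Every clone is forced to be present in at least one sample, since
#' clone trees derived from SNV clustering only contain detected clones.
#'
#' @param tree a `clone_tree`
#' @param config a [sim_config()]
#' @return a `clone_proportions` matrix.
#' @export
simulate_proportions <- function(tree, config) {
  maybe_seed(config)
  tum <- tumour_clones(tree)
  k <- config$n_samples
  samples <- paste0("S", seq_len(k))
  keep <- 1 - config$sparsity
  present <- matrix(FALSE, length(tum), k, dimnames = list(tum, samples))
  for (r in seq_len(k)) {
    for (cl in tum) {
      pa <- tree$parent[[cl]]
      p_keep <- if (pa == "diploid" || present[pa, r]) keep else keep / 2
      present[cl, r] <- cl == mrca_clone(tree) || stats::runif(1) < p_keep
    }
  }
  for (cl in tum[rowSums(present) == 0])
    present[cl, sample.int(k, 1L)] <- TRUE
  purity <- stats::runif(k, config$purity_range[1], config$purity_range[2])
  u <- matrix(0, length(tum) + 1L, k,
              dimnames = list(c("diploid", tum), samples))
  for (r in seq_len(k)) {
    w <- stats::rgamma(sum(present[, r]), shape = config$dirichlet_alpha)
    w <- w / sum(w)
    u[rownames(present)[present[, r]], r] <- purity[r] * w
    u["diploid", r] <- 1 - purity[r]
  }
  clone_proportions(u, tree = tree)
}

#' Simulate observed fractional copy numbers with read-count noise
#'
#' Per segment and sample, the true tumour mixture
#' \eqn{x = \sum_i c^A_i u_i}, \eqn{y = \sum_i c^B_i u_i}, \eqn{f = x + y}
#' is observed through a Poisson read-depth draw
#' \eqn{t \sim \mathrm{Pois}(f/\rho\cdot\gamma)} (with \eqn{\rho} the
#' length-weighted all-cell ploidy of the sample) and a binomial BAF draw
#' \eqn{\hat\beta = \mathrm{Binom}(\gamma, y/f)/\gamma}. The observed values
#' are reconstructed as \eqn{\hat F = (t/\gamma)\rho},
#' \eqn{\hat x = \hat F(1-\hat\beta)}, \eqn{\hat y = \hat F\hat\beta}, and
#' interval bounds are the estimates \eqn{\pm\, z\,\sigma} floored at 0.
#'
#' @param truth list with `profile`, `segments` (from
#'   [simulate_tree_and_profile()]) and `proportions`.
#' @param config a [sim_config()]
#' @param literal_scaling reproduce the unnormalized reconstruction
#'   \eqn{\hat x = t\,\rho\,(1-\hat\beta)} (coverage-inflated; compatibility
#'   only).
#' @return list with `fractional` (a `fractional_cn` table) and `truth`
#'   (matrices `x`, `y`, `f`, `beta` and the per-sample `rho`).
#' @export
simulate_reads <- function(truth, config, literal_scaling = FALSE) {
  maybe_seed(config)
  mix <- mixture_fractional(truth$profile, truth$proportions)
  x <- mix$A; y <- mix$B
  f <- x + y
  segments <- truth$segments
  w <- segments$length
  u0 <- truth$proportions["diploid", ]
  rho <- colSums(w * f) / sum(w) + 2 * u0     # all-cell average total CN
  gamma <- config$coverage
  beta <- ifelse(f > 0, y / f, 0)
  rows <- list()
  for (r in colnames(x)) {
    mu <- pmax(f[, r], 0.02) / rho[r] * gamma
    t_r <- stats::rpois(nrow(segments), mu)
    bhat <- stats::rbinom(nrow(segments), gamma, beta[, r]) / gamma
    Fhat <- if (literal_scaling) t_r * rho[r] else (t_r / gamma) * rho[r]
    xhat <- Fhat * (1 - bhat); yhat <- Fhat * bhat
    half <- config$z * config$noise_sd
    rows[[r]] <- data.frame(
      segment = segments$segment, chrom = segments$chrom,
      start = segments$start, end = segments$end, sample = r,
      fA = xhat, fA_lo = pmax(xhat - half, 0), fA_hi = xhat + half,
      fB = yhat, fB_lo = pmax(yhat - half, 0), fB_hi = yhat + half,
      stringsAsFactors = FALSE)
  }
  fractional <- fractional_cn(do.call(rbind, rows), segments = segments)
  list(fractional = fractional,
       truth = list(x = x, y = y, f = f, beta = beta, rho = rho,
                    gamma = gamma))
}

#' Simulate a complete multi-sample tumour
#'
#' Runs [simulate_tree_and_profile()], [simulate_proportions()] and
#' [simulate_reads()] under a single seed.
#'
#' @param config a [sim_config()]
#' @return list with `tree`, `segments`, `profile`, `proportions`,
#'   `fractional`, `truth`, `wgd` and `config`.
#' @export
simulate_tumour <- function(config = sim_config()) {
  maybe_seed(config)
  config_inner <- config; config_inner$seed <- NULL
  tp <- simulate_tree_and_profile(config_inner)
  u <- simulate_proportions(tp$tree, config_inner)
  obs <- simulate_reads(list(profile = tp$profile, segments = tp$segments,
                             proportions = u), config_inner)
  list(tree = tp$tree, segments = tp$segments, profile = tp$profile,
       proportions = u, fractional = obs$fractional, truth = obs$truth,
       wgd = tp$wgd, config = config)
}

#' Export a simulated tumour to the package's file formats
#'
#' Writes `tree.tsv`, `proportions.tsv`, `fractional_cn.tsv`, the
#' ground-truth `clone_cn.tsv` and a `manifest.yaml` with the configuration
#' and seed.
#'
#' @param sim result of [simulate_tumour()]
#' @param dir output directory (created if missing)
#' @export
export_truth <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tree_tsv(sim$tree, file.path(dir, "tree.tsv"))
  up <- data.frame(clone = rep(rownames(sim$proportions),
                               ncol(sim$proportions)),
                   sample = rep(colnames(sim$proportions),
                                each = nrow(sim$proportions)),
                   proportion = as.vector(sim$proportions))
  utils::write.table(up, file.path(dir, "proportions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$fractional, file.path(dir, "fractional_cn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_clone_profile(sim$profile, sim$segments,
                      file.path(dir, "clone_cn.tsv"))
  cfg <- sim$config; class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
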