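## state sets: per segment, the distinct (cA, cB) pairs across tumour clones
state_strings <- function(profile, seg, clones) {
  unique(paste(profile$A[seg, clones], profile$B[seg, clones]))
}

#' Length-weighted state-set accuracy
#'
#' Per segment, the Jaccard index between the sets of distinct allele-specific
#' copy-number states across tumour clones in the two profiles, averaged with
#' segment-length weights:
#' \deqn{\mathrm{Accuracy} = \frac{1}{L}\sum_s l_s
#'   \frac{|S_s \cap T_s|}{|S_s \cup T_s|}.}
#' Invariant to clone relabelling.
#'
#' @param truth,pred `clone_cn_profile`s over the same segments.
#' @param segments a `segment_table`.
#' @return accuracy in \[0, 1\].
#' @export
cn_accuracy <- function(truth, pred, segments) {
  if (!setequal(rownames(truth$A), rownames(pred$A)))
    stop("profiles cover different segments")
  tc <- setdiff(colnames(truth$A), "diploid")
  pc <- setdiff(colnames(pred$A), "diploid")
  w <- segments[segments$segment, "length"]
  jac <- vapply(segments$segment, function(s) {
    T_s <- state_strings(truth, s, tc)
    S_s <- state_strings(pred, s, pc)
    length(intersect(S_s, T_s)) / length(union(S_s, T_s))
  }, numeric(1))
  sum(w * jac) / sum(w)
}

#' Matched-clone Hamming distance
#'
#' For each true tumour clone, the minimum normalized Hamming distance (the
#' fraction of mismatching (segment, allele) entries, optionally
#' length-weighted) to any predicted tumour clone; returns the mean over
#' true clones. Extra predicted clones are never penalized.
#'
#' @param truth,pred `clone_cn_profile`s over the same segments.
#' @param segments required when `length_weighted = TRUE`.
#' @param length_weighted weight mismatches by segment length.
#' @return mean matched Hamming distance in \[0, 1\].
#' @export
matched_clone_hd <- function(truth, pred, length_weighted = FALSE,
                             segments = NULL) {
  segs <- rownames(truth$A)
  if (!setequal(segs, rownames(pred$A)))
    stop("profiles cover different segments")
  tc <- setdiff(colnames(truth$A), "diploid")
  pc <- setdiff(colnames(pred$A), "diploid")
  if (!length(pc)) stop("predicted profile has no tumour clones")
  w <- if (length_weighted) {
    if (is.null(segments)) stop("length weighting requires a segment table")
    rep(segments[segs, "length"], 2)
  } else rep(1, 2 * length(segs))
  tv <- function(p, cl) c(p$A[segs, cl], p$B[segs, cl])
  per_true <- vapply(tc, function(ti) {
    v <- tv(truth, ti)
    min(vapply(pc, function(pi)
      sum(w * (v != tv(pred, pi))) / sum(w), numeric(1)))
  }, numeric(1))
  mean(per_true)
}

## distribution over states for one segment and sample: mass of each (cA,cB)
## state among tumour clones, renormalized by purity (cancer cells only)
state_distribution <- function(profile, proportions, seg, sample) {
  tum <- setdiff(colnames(profile$A), "diploid")
  u <- proportions[tum, sample]
  pur <- sum(u)
  if (pur <= 0) return(NULL)
  states <- paste(profile$A[seg, tum], profile$B[seg, tum])
  mass <- tapply(u / pur, states, sum)
  mass[mass > 0]
}

#' Mean total variation distance between copy-number state distributions
#'
#' Per segment and sample, each (profile, proportions) pair induces a
#' probability distribution over allele-specific copy-number states (clone
#' proportions renormalized by purity, so distributions are over cancer
#' cells); the TVD is \eqn{\frac12\sum_c |P(c) - Q(c)|}. Returns the mean
#' over all (segment, sample) pairs with nonzero purity.
#'
#' @param truth,pred `clone_cn_profile`s over the same segments.
#' @param u_truth,u_pred `clone_proportions` for the two profiles (same
#'   samples).
#' @return mean TVD in \[0, 1\].
#' @export
tvd <- function(truth, u_truth, pred, u_pred) {
  segs <- rownames(truth$A)
  if (!setequal(segs, rownames(pred$A)))
    stop("profiles cover different segments")
  samples <- colnames(u_truth)
  if (!setequal(samples, colnames(u_pred)))
    stop("proportion matrices cover different samples")
  vals <- c()
  for (s in segs) for (r in samples) {
    P <- state_distribution(truth, u_truth, s, r)
    Q <- state_distribution(pred, u_pred, s, r)
    if (is.null(P) || is.null(Q)) next
    states <- union(names(P), names(Q))
    p <- ifelse(states %in% names(P), P[states], 0)
    q <- ifelse(states %in% names(Q), Q[states], 0)
    vals <- c(vals, 0.5 * sum(abs(p - q)))
  }
  mean(vals)
}
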