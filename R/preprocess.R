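#' Aggregate bin-level depth and BAF to segments
#'
#' A bin contributes to every segment it overlaps by at least 1 bp (no length
#' weighting): per segment and sample, the mean read depth and mean BAF over
#' overlapping bins.
#'
#' @param bins data.frame `chrom, start, end, sample, depth, baf`.
#' @param segments a `segment_table`.
#' @return data.frame `segment, sample, depth, baf`.
#' @export
aggregate_bins <- function(bins, segments) {
  stopifnot(all(c("chrom", "start", "end", "sample", "depth", "baf") %in%
                  names(bins)))
  if (any(bins$depth < 0)) stop("bin depths must be non-negative")
  if (any(bins$baf < 0 | bins$baf > 1)) stop("bin BAF must lie in [0, 1]")
  samples <- sort(unique(bins$sample))
  out <- vector("list", 0L)
  for (ch in unique(segments$chrom)) {
    seg_i <- which(segments$chrom == ch)
    bin_i <- which(bins$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(segments$start[seg_i], segments$end[seg_i]),
      IRanges::IRanges(bins$start[bin_i], bins$end[bin_i]))
    for (k in seq_along(seg_i)) {
      seg <- segments$segment[seg_i[k]]
      b <- bin_i[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]]
      for (sm in samples) {
        bs <- b[bins$sample[b] == sm]
        if (!length(bs))
          stop("segment ", seg, " has no overlapping bins in sample ", sm)
        out[[length(out) + 1L]] <- data.frame(
          segment = seg, sample = sm,
          depth = mean(bins$depth[bs]), baf = mean(bins$baf[bs]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Scale segment read depth to fractional copy numbers
#'
#' Per segment and sample the scaling factor is the ratio of the reference
#' fractional copy number to the observed depth; its per-sample mean over
#' segments rescales depth into total fractional copy number, which the BAF
#' splits into alleles:
#' \deqn{\Gamma_{s,r} = F_{T,s,r}/R_{s,r},\quad
#'       \bar\Gamma_r = \mathrm{mean}_s\,\Gamma_{s,r},\quad
#'       F_{s,r} = \bar\Gamma_r R_{s,r},\quad
#'       F^A = F(1-B),\; F^B = F B.}
#'
#' @param agg data.frame `segment, sample, depth, baf` from [aggregate_bins()].
#' @param f_ref data.frame `segment, sample, f_total` of reference total
#'   fractional copy numbers.
#' @return data.frame `segment, sample, F, FA, FB`.
#' @export
scale_depth_to_fractional <- function(agg, f_ref) {
  m <- merge(agg, f_ref, by = c("segment", "sample"))
  if (nrow(m) != nrow(agg))
    stop("reference fractional CN missing for some (segment, sample) pairs")
  if (any(m$depth <= 0))
    stop("zero read depth for segment(s): ",
         paste(unique(m$segment[m$depth <= 0]), collapse = ", "))
  m$gamma <- m$f_total / m$depth
  gbar <- tapply(m$gamma, m$sample, mean)
  m$F <- as.numeric(gbar[m$sample]) * m$depth
  m$FA <- m$F * (1 - m$baf)
  m$FB <- m$F * m$baf
  m[order(m$segment, m$sample), c("segment", "sample", "F", "FA", "FB")]
}

## one-sample t test of replicate values against the nearest integer of
## their mean; NA when untestable (<2 values or zero spread)
.t_vs_nearest_int <- function(v) {
  if (length(v) < 2 || stats::sd(v) == 0) return(NA_real_)
  stats::t.test(v, mu = round(mean(v)))$p.value
}

#' Flag segments as clonal or subclonal
#'
#' A segment is subclonal when, for either allele in any sample, a one-sample
#' t-test rejects (at `alpha`) that the within-segment replicate fractional
#' copy numbers are centred on their nearest integer. Segments without enough
#' replicates anywhere are flagged untestable and treated as clonal.
#'
#' @param replicates data.frame `segment, sample, allele, value` of
#'   within-segment replicate estimates (e.g. SNP-level).
#' @param alpha rejection threshold (default `1e-4`).
#' @return data.frame `segment, status` with status in
#'   `clonal / subclonal / untestable`.
#' @export
classify_clonality <- function(replicates, alpha = 1e-4) {
  stopifnot(all(c("segment", "sample", "allele", "value") %in% names(replicates)))
  segs <- unique(replicates$segment)
  status <- vapply(segs, function(s) {
    d <- replicates[replicates$segment == s, ]
    p <- unlist(lapply(split(d$value, list(d$sample, d$allele), drop = TRUE),
                       .t_vs_nearest_int))
    if (all(is.na(p))) return("untestable")
    if (any(p < alpha, na.rm = TRUE)) "subclonal" else "clonal"
  }, character(1))
  data.frame(segment = segs, status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Test segments for allelic imbalance
#'
#' A segment is imbalanced when a two-sample t-test rejects (at `alpha`)
#' equality of the two alleles' replicate fractional copy numbers in at least
#' one sample. Insufficient replicates give `untestable` (treated as
#' balanced).
#'
#' @inheritParams classify_clonality
#' @param alpha rejection threshold (default `1e-3`).
#' @return data.frame `segment, status` with status in
#'   `balanced / imbalanced / untestable`.
#' @export
test_allelic_imbalance <- function(replicates, alpha = 1e-3) {
  segs <- unique(replicates$segment)
  status <- vapply(segs, function(s) {
    d <- replicates[replicates$segment == s, ]
    p <- vapply(unique(d$sample), function(sm) {
      a <- d$value[d$sample == sm & d$allele == "A"]
      b <- d$value[d$sample == sm & d$allele == "B"]
      if (length(a) < 2 || length(b) < 2 ||
          (stats::sd(a) == 0 && stats::sd(b) == 0)) return(NA_real_)
      stats::t.test(a, b)$p.value
    }, numeric(1))
    if (all(is.na(p))) return("untestable")
    if (any(p < alpha, na.rm = TRUE)) "imbalanced" else "balanced"
  }, character(1))
  data.frame(segment = segs, status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Rebalance alleles of subclonal, allele-balanced segments
#'
#' For every (segment, sample) row of a segment flagged subclonal and
#' balanced: if both allele estimates exceed their nearest integers, allele B
#' is fixed to its nearest integer; if both fall below, allele A is. The
#' other allele receives its own nearest integer plus the remainder
#' `total - nintA - nintB`, so the total fractional copy number is conserved.
#' Rows where one allele is above and the other below its nearest integer
#' are left unchanged and recorded in the `"skipped"` attribute. Interval
#' bounds are shifted together with their estimate.
#'
#' @param fractional a `fractional_cn` table.
#' @param clonality data.frame from [classify_clonality()].
#' @param imbalance data.frame from [test_allelic_imbalance()].
#' @return the adjusted `fractional_cn` table.
#' @export
rebalance_alleles <- function(fractional, clonality, imbalance) {
  ## untestable imbalance is treated as balanced; untestable clonality is
  ## treated as clonal (and hence excluded)
  eligible <- intersect(
    clonality$segment[clonality$status == "subclonal"],
    imbalance$segment[imbalance$status %in% c("balanced", "untestable")])
  skipped <- character(0)
  for (i in which(fractional$segment %in% eligible)) {
    fA <- fractional$fA[i]; fB <- fractional$fB[i]
    nA <- round(fA); nB <- round(fB)
    total <- fA + fB
    if (fA >= nA && fB >= nB) {        # both above: fix B to its integer
      newB <- nB; newA <- nA + (total - nA - nB)
    } else if (fA <= nA && fB <= nB) { # both below: fix A to its integer
      newA <- nA; newB <- nB + (total - nA - nB)
    } else {
      skipped <- c(skipped,
                   paste0(fractional$segment[i], ":", fractional$sample[i]))
      next
    }
    fractional$fA_lo[i] <- fractional$fA_lo[i] + (newA - fA)
    fractional$fA_hi[i] <- fractional$fA_hi[i] + (newA - fA)
    fractional$fB_lo[i] <- fractional$fB_lo[i] + (newB - fB)
    fractional$fB_hi[i] <- fractional$fB_hi[i] + (newB - fB)
    fractional$fA[i] <- newA; fractional$fB[i] <- newB
  }
  fractional$fA_lo <- pmax(fractional$fA_lo, 0)
  fractional$fB_lo <- pmax(fractional$fB_lo, 0)
  attr(fractional, "skipped") <- skipped
  fractional
}

#' Homozygous-deletion eligibility per (segment, clone)
#'
#' A clone may take the (0,0) state in a segment only when the segment is
#' shorter than `max_len` (50 Mb) and the clone or one of its descendants is
#' present in a sample whose fractional copy number is below `h` on both
#' alleles.
#'
#' @param tree a `clone_tree`
#' @param proportions a `clone_proportions` matrix
#' @param fractional a `fractional_cn` table
#' @param segments a `segment_table`
#' @param h fractional copy-number threshold (default 1)
#' @param max_len maximum eligible segment length in bp (default 5e7)
#' @return logical matrix (segments x tumour clones).
#' @export
homdel_eligibility <- function(tree, proportions, fractional, segments,
                               h = 1, max_len = 5e7) {
  fr <- fractional_matrices(fractional, segments,
                            samples = colnames(proportions))
  low <- fr$fA < h & fr$fB < h              # segments x samples
  tum <- tumour_clones(tree)
  elig <- matrix(FALSE, nrow(segments), length(tum),
                 dimnames = list(segments$segment, tum))
  for (cl in tum) {
    grp <- tree_descendants(tree, cl, include_self = TRUE)
    present <- colSums(proportions[grp, , drop = FALSE]) > 0   # per sample
    if (any(present))
      elig[, cl] <- rowSums(low[, present, drop = FALSE]) > 0
  }
  elig[segments$length >= max_len, ] <- FALSE
  elig
}
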