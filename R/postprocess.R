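#' Clone ploidy
#'
#' Segment-length-weighted mean total copy number per clone:
#' \eqn{p_i = \sum_s w_s (c^A_{s,i}+c^B_{s,i}) / \sum_s w_s}.
#'
#' @param profile a `clone_cn_profile`
#' @param segments a `segment_table`
#' @return named numeric vector over all clones (diploid included, = 2).
#' @export
clone_ploidy <- function(profile, segments) {
  w <- segments[rownames(profile$A), "length"]
  colSums(w * (profile$A + profile$B)) / sum(w)
}

#' Detect whole-genome-doubled clones
#'
#' A clone is flagged when the segment-length-weighted mean ratio of its
#' total copy number to its parent's exceeds 1.5; failing that, when the
#' ratio to its grandparent exceeds 1.5 while the parent is itself unflagged
#' (a doubling spread over two edges). Segments where the reference clone has
#' total copy number 0 are excluded from the mean; the MRCA is compared to
#' the diploid root and has no grandparent.
#'
#' @param profile a `clone_cn_profile`
#' @param tree a `clone_tree`
#' @param segments a `segment_table`
#' @return named logical vector over tumour clones.
#' @export
detect_wgd <- function(profile, tree, segments) {
  tot <- profile$A + profile$B
  w <- segments[rownames(tot), "length"]
  wratio <- function(child, ref) {
    keep <- tot[, ref] > 0
    if (!any(keep)) return(NA_real_)
    sum(w[keep] * tot[keep, child] / tot[keep, ref]) / sum(w[keep])
  }
  flags <- stats::setNames(logical(0), character(0))
  for (cl in tumour_clones(tree)) {           # preorder: parent flag known
    pa <- tree$parent[[cl]]
    flagged <- isTRUE(wratio(cl, pa) > 1.5)
    if (!flagged) {
      gp <- tree$parent[[pa]]
      if (!is.na(gp) && !isTRUE(flags[pa]))
        flagged <- isTRUE(wratio(cl, gp) > 1.5)
    }
    flags[cl] <- flagged
  }
  flags
}

#' Call copy-number events on every edge and segment
#'
#' Per edge (parent -> child) and segment: gain if either allele increases,
#' loss if either decreases, LOH if an allele goes from > 0 to 0,
#' amplification if for either allele
#' \eqn{c_j > 2 c_i}, \eqn{c_j \ge 4} and \eqn{c_j > p_j} (child ploidy).
#' Per-allele flags are kept alongside the combined calls for arm-level
#' aggregation.
#'
#' @param profile a `clone_cn_profile`
#' @param tree a `clone_tree`
#' @param segments a `segment_table`
#' @param ploidy optional precomputed [clone_ploidy()] vector.
#' @return data.frame of class `edge_event_table`, one row per
#'   (edge, segment).
#' @export
call_segment_events <- function(profile, tree, segments, ploidy = NULL) {
  if (is.null(ploidy)) ploidy <- clone_ploidy(profile, segments)
  rows <- lapply(tumour_clones(tree), function(ch) {
    pa <- tree$parent[[ch]]
    cAp <- profile$A[, pa]; cBp <- profile$B[, pa]
    cAc <- profile$A[, ch]; cBc <- profile$B[, ch]
    ampA <- cAc > 2 * cAp & cAc >= 4 & cAc > ploidy[ch]
    ampB <- cBc > 2 * cBp & cBc >= 4 & cBc > ploidy[ch]
    data.frame(parent = pa, child = ch, segment = rownames(profile$A),
               deltaA = cAc - cAp, deltaB = cBc - cBp,
               gainA = cAc > cAp, gainB = cBc > cBp,
               lossA = cAc < cAp, lossB = cBc < cBp,
               lohA = cAp > 0 & cAc == 0, lohB = cBp > 0 & cBc == 0,
               ampA = ampA, ampB = ampB,
               gain = cAc > cAp | cBc > cBp,
               loss = cAc < cAp | cBc < cBp,
               loh = (cAp > 0 & cAc == 0) | (cBp > 0 & cBc == 0),
               amplification = ampA | ampB,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("edge_event_table", "data.frame")
  out
}

#' Aggregate segment events to chromosome-arm events per edge
#'
#' An arm event is called per edge when, for a single allele, at least 90%
#' of the arm's analysed length (sum of its segment lengths) is affected by
#' gain / loss / amplification; arm LOH additionally requires at most 20% of
#' the arm at copy number 0 in the parent, per allele.
#'
#' @param events an `edge_event_table` from [call_segment_events()]
#' @param profile a `clone_cn_profile`
#' @param tree a `clone_tree`
#' @param segments a `segment_table` with an `arm` column.
#' @param gain_frac,loh_child_frac coverage threshold (default 0.9)
#' @param loh_parent_frac parent zero-coverage ceiling for LOH (default 0.2)
#' @return data.frame, one row per (edge, chromosome, arm).
#' @export
call_arm_events <- function(events, profile, tree, segments,
                            gain_frac = 0.9, loh_child_frac = 0.9,
                            loh_parent_frac = 0.2) {
  if (!"arm" %in% names(segments) || all(is.na(segments$arm)))
    stop("segment table has no arm labels")
  seg <- segments[match(events$segment, segments$segment), ]
  events$chrom <- seg$chrom; events$arm <- seg$arm; events$w <- seg$length
  key <- interaction(events$parent, events$child, events$chrom, events$arm,
                     drop = TRUE)
  rows <- lapply(split(events, key), function(d) {
    W <- sum(d$w)
    if (W == 0) return(NULL)
    frac <- function(flag) sum(d$w[flag]) / W
    pa0A <- frac(profile$A[d$segment, d$parent[1]] == 0)
    pa0B <- frac(profile$B[d$segment, d$parent[1]] == 0)
    ch0A <- frac(profile$A[d$segment, d$child[1]] == 0)
    ch0B <- frac(profile$B[d$segment, d$child[1]] == 0)
    data.frame(parent = d$parent[1], child = d$child[1],
               chrom = d$chrom[1], arm = d$arm[1],
               gain = frac(d$gainA) >= gain_frac | frac(d$gainB) >= gain_frac,
               loss = frac(d$lossA) >= gain_frac | frac(d$lossB) >= gain_frac,
               loh = (ch0A >= loh_child_frac & pa0A <= loh_parent_frac) |
                     (ch0B >= loh_child_frac & pa0B <= loh_parent_frac),
               amplification = frac(d$ampA) >= gain_frac |
                               frac(d$ampB) >= gain_frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample-level chromosome-arm LOH calls from fractional copy numbers
#'
#' An arm is called LOH in a sample when at least `genome_frac` (0.98) of its
#' analysed length has a fractional copy number below `cn_cut` (0.5) for a
#' single allele.
#'
#' @param fractional a `fractional_cn` table
#' @param segments a `segment_table` with `arm` labels
#' @param genome_frac,cn_cut thresholds
#' @return data.frame `sample, chrom, arm, loh`.
#' @export
sample_level_arm_loh <- function(fractional, segments, genome_frac = 0.98,
                                 cn_cut = 0.5) {
  seg <- segments[match(fractional$segment, segments$segment), ]
  fractional$chrom <- seg$chrom; fractional$arm <- seg$arm
  fractional$w <- seg$length
  key <- interaction(fractional$sample, fractional$chrom, fractional$arm,
                     drop = TRUE)
  rows <- lapply(split(as.data.frame(fractional), key), function(d) {
    W <- sum(d$w)
    data.frame(sample = d$sample[1], chrom = d$chrom[1], arm = d$arm[1],
               loh = sum(d$w[d$fA < cn_cut]) / W >= genome_frac |
                     sum(d$w[d$fB < cn_cut]) / W >= genome_frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count SCNAs per tree edge by merging contiguous equal deltas
#'
#' Per allele and chromosome, maximal runs of consecutive segments (in
#' genomic order) whose parent-to-child copy-number delta is identical and
#' positive count as one gain each; identical negative deltas count as one
#' loss each. `n_scnas` is the total over chromosomes and alleles. A change
#' of amplitude breaks the run; arm boundaries do not.
#'
#' @param profile a `clone_cn_profile`
#' @param tree a `clone_tree`
#' @param segments a `segment_table`
#' @return data.frame `parent, child, n_gains, n_losses, n_scnas`.
#' @export
count_scnas_per_edge <- function(profile, tree, segments) {
  ord <- segments$segment
  chrom <- segments$chrom
  rows <- lapply(tumour_clones(tree), function(ch) {
    pa <- tree$parent[[ch]]
    gains <- 0L; losses <- 0L
    for (al in c("A", "B")) {
      delta <- profile[[al]][ord, ch] - profile[[al]][ord, pa]
      for (cx in unique(chrom)) {
        r <- rle(delta[chrom == cx])
        gains <- gains + sum(r$values > 0)
        losses <- losses + sum(r$values < 0)
      }
    }
    data.frame(parent = pa, child = ch, n_gains = gains, n_losses = losses,
               n_scnas = gains + losses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify clones by primary/metastatic sample sharing
#'
#' Presence follows mutation-sharing semantics: a clone is detected in a
#' sample when it or any descendant has proportion above `threshold` there.
#' Shared clones are detected in at least one primary and one metastatic
#' sample (lymph nodes count as metastatic); seeding clones are the most
#' recent shared clones (shared, with no shared descendant); the remainder
#' are primary- or metastasis-specific by exclusive detection.
#'
#' @param tree a `clone_tree`
#' @param proportions a `clone_proportions` matrix
#' @param sites named character vector over samples with values `primary`,
#'   `metastasis` or `lymph_node`.
#' @param threshold presence threshold on clone proportion (default 0).
#' @return data.frame `clone, is_mrca, is_shared, is_seeding, class`; `class`
#'   is one of `MRCA`, `seeding`, `shared`, `primary_specific`,
#'   `metastasis_specific`.
#' @export
classify_clones <- function(tree, proportions, sites, threshold = 0) {
  stopifnot(all(colnames(proportions) %in% names(sites)),
            all(sites %in% c("primary", "metastasis", "lymph_node")))
  sites <- sites[colnames(proportions)]
  prim <- sites == "primary"
  met <- !prim
  tum <- tumour_clones(tree)
  detected <- t(vapply(tum, function(cl) {
    grp <- tree_descendants(tree, cl, include_self = TRUE)
    colSums(proportions[grp, , drop = FALSE] > threshold) > 0
  }, logical(ncol(proportions))))
  in_prim <- rowSums(detected[, prim, drop = FALSE]) > 0
  in_met <- rowSums(detected[, met, drop = FALSE]) > 0
  shared <- in_prim & in_met
  seeding <- vapply(tum, function(cl) {
    shared[cl] && !any(shared[intersect(tree_descendants(tree, cl), tum)])
  }, logical(1))
  cls <- ifelse(tum == mrca_clone(tree), "MRCA",
         ifelse(seeding, "seeding",
         ifelse(shared, "shared",
         ifelse(in_met & !in_prim, "metastasis_specific", "primary_specific"))))
  data.frame(clone = tum, is_mrca = tum == mrca_clone(tree),
             is_shared = unname(shared), is_seeding = unname(seeding),
             class = unname(cls), stringsAsFactors = FALSE, row.names = NULL)
}

#' Drop clones found exclusively in lymph-node samples
#'
#' @param proportions a `clone_proportions` matrix
#' @param sites named site vector as in [classify_clones()]
#' @param threshold presence threshold
#' @return character vector of retained tumour clone IDs.
#' @export
drop_lymph_only <- function(proportions, sites, threshold = 0) {
  sites <- sites[colnames(proportions)]
  tum <- setdiff(rownames(proportions), "diploid")
  keep <- vapply(tum, function(cl) {
    pres <- proportions[cl, ] > threshold
    !any(pres) || any(pres & sites != "lymph_node")
  }, logical(1))
  tum[keep]
}

#' Clone copy-number diversity (CCD)
#'
#' The maximum pairwise Euclidean distance between the clones' concatenated
#' allele-A and allele-B copy-number vectors over genomically sorted
#' segments. Entries are unweighted by segment length by default.
#'
#' @param profile a `clone_cn_profile`
#' @param clones tumour clones to include (default: all tumour clones; pass
#'   the result of [drop_lymph_only()] to apply the lymph-node exclusion).
#' @param length_weighted weight each segment's entries by `sqrt(length)`
#'   so squared differences are length-weighted.
#' @param segments required when `length_weighted = TRUE`.
#' @return the CCD score (0 for a single clone).
#' @export
compute_ccd <- function(profile, clones = NULL, length_weighted = FALSE,
                        segments = NULL) {
  if (is.null(clones)) clones <- setdiff(colnames(profile$A), "diploid")
  if (!length(clones)) stop("CCD needs at least one clone")
  V <- rbind(profile$A[, clones, drop = FALSE],
             profile$B[, clones, drop = FALSE])
  if (length_weighted) {
    if (is.null(segments)) stop("length weighting requires a segment table")
    w <- segments[rownames(profile$A), "length"]
    V <- V * sqrt(rep(w / mean(w), 2))
  }
  if (length(clones) == 1L) return(0)
  max(stats::dist(t(V)))
}
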