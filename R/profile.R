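#' Construct a clone copy-number profile
#'
#' @param A,B integer matrices (segments x clones) of allele-specific copy
#'   numbers. Column names are clone IDs and must include `"diploid"`, whose
#'   entries are all 1. Row names are segment IDs.
#' @return list of class `clone_cn_profile` with components `A` and `B`.
#' @export
clone_cn_profile <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B)) || !identical(dimnames(A), dimnames(B)))
    stop("allele matrices must have identical dimensions and dimnames")
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stop("profile matrices need segment rownames and clone colnames")
  if (anyNA(A) || anyNA(B)) stop("profile contains missing values")
  if (any(A < 0) || any(B < 0) || any(A != round(A)) || any(B != round(B)))
    stop("copy numbers must be non-negative integers")
  if (!"diploid" %in% colnames(A))
    stop("profile must include the normal clone 'diploid'")
  if (any(A[, "diploid"] != 1) || any(B[, "diploid"] != 1))
    stop("the diploid clone must have copy number (1,1) in every segment")
  structure(list(A = A, B = B), class = "clone_cn_profile")
}

#' @export
print.clone_cn_profile <- function(x, ...) {
  cat("clone_cn_profile:", nrow(x$A), "segments x", ncol(x$A) - 1L,
      "tumour clones\n")
  invisible(x)
}

#' Check loss-of-heterozygosity persistence along every edge
#'
#' LOH is irreversible: a parent copy number of 0 forces 0 in the child, per
#' allele and segment.
#'
#' @param profile a `clone_cn_profile`
#' @param tree a `clone_tree`
#' @return `TRUE` (invisibly) or an error naming the first violation.
#' @export
check_loh_persistence <- function(profile, tree) {
  for (al in c("A", "B")) {
    M <- profile[[al]]
    for (ch in tumour_clones(tree)) {
      pa <- tree$parent[[ch]]
      bad <- M[, pa] == 0 & M[, ch] > 0
      if (any(bad))
        stop(sprintf("LOH persistence violated: allele %s, edge %s->%s, segment %s",
                     al, pa, ch, rownames(M)[which(bad)[1L]]))
    }
  }
  invisible(TRUE)
}

#' Predicted fractional copy numbers of a profile under given proportions
#'
#' Computes \eqn{f^A_{s,r} = \sum_{i \ge 1} c^A_{s,i} u_{i,r}} (and
#' analogously for allele B): the clone-proportion-weighted sum over tumour
#' clones. The normal clone is excluded and no purity renormalization is
#' applied, matching the convention of the input fractional-CN tables.
#'
#' @param profile a `clone_cn_profile`
#' @param proportions a `clone_proportions` matrix with the same clone set.
#' @return list with matrices `A` and `B` (segments x samples).
#' @export
mixture_fractional <- function(profile, proportions) {
  if (!setequal(colnames(profile$A), rownames(proportions)))
    stop("clone sets of profile and proportions differ")
  tum <- setdiff(colnames(profile$A), "diploid")
  u <- proportions[tum, , drop = FALSE]
  list(A = profile$A[, tum, drop = FALSE] %*% u,
       B = profile$B[, tum, drop = FALSE] %*% u)
}

#' Write a clone copy-number profile as a long-format TSV
#'
#' One row per (segment, clone): `segment chrom start end clone cnA cnB`,
#' ordered genomically then by clone ID.
#'
#' @param profile a `clone_cn_profile`
#' @param segments a `segment_table` covering all profile segments.
#' @param path output path
#' @export
write_clone_profile <- function(profile, segments, path) {
  miss <- setdiff(segments$segment, rownames(profile$A))
  if (length(miss))
    stop("profile is missing segment(s): ", paste(miss, collapse = ", "))
  clones <- sort(colnames(profile$A))
  df <- data.frame(
    segment = rep(segments$segment, each = length(clones)),
    chrom = rep(segments$chrom, each = length(clones)),
    start = rep(segments$start, each = length(clones)),
    end = rep(segments$end, each = length(clones)),
    clone = rep(clones, times = nrow(segments)),
    stringsAsFactors = FALSE)
  df$cnA <- profile$A[cbind(df$segment, df$clone)]
  df$cnB <- profile$B[cbind(df$segment, df$clone)]
  if (anyNA(df$cnA) || anyNA(df$cnB)) {
    i <- which(is.na(df$cnA) | is.na(df$cnB))[1L]
    stop(sprintf("profile incomplete for (segment %s, clone %s)",
                 df$segment[i], df$clone[i]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clone copy-number profile written by [write_clone_profile()]
#'
#' @param path TSV path
#' @return list with `profile` (a `clone_cn_profile`) and `segments`.
#' @export
read_clone_profile <- function(path) {
  df <- utils::read.delim(path, colClasses = c(segment = "character",
                                               clone = "character"))
  segments <- segment_table(unique(df[, c("segment", "chrom", "start", "end")]))
  clones <- sort(unique(df$clone))
  mk <- function(col) {
    m <- matrix(NA_real_, nrow(segments), length(clones),
                dimnames = list(segments$segment, clones))
    m[cbind(df$segment, df$clone)] <- df[[col]]
    m
  }
  list(profile = clone_cn_profile(mk("cnA"), mk("cnB")), segments = segments)
}

#' Round-a-sample baseline for clone copy numbers
#'
#' For each clone, take the sample in which the clone is most prevalent and
#' round that sample's fractional copy numbers to the nearest integer
#' (half-to-even). Clones absent from every sample inherit the copy number of
#' their closest ancestor with an assigned state; if no ancestor has one, the
#' state of the clone's first child is used.
#'
#' @param fractional a `fractional_cn` table
#' @param proportions a `clone_proportions` matrix
#' @param tree a `clone_tree`
#' @param segments a `segment_table`
#' @return a `clone_cn_profile`
#' @export
simple_model_baseline <- function(fractional, proportions, tree, segments) {
  fm <- fractional_matrices(fractional, segments,
                            samples = colnames(proportions))
  tum <- tumour_clones(tree)
  m <- nrow(segments)
  A <- matrix(NA_real_, m, length(tum), dimnames = list(segments$segment, tum))
  B <- A
  for (cl in tum) {
    u <- proportions[cl, ]
    if (max(u) > 0) {
      r <- which.max(u)
      A[, cl] <- round(fm$fA[, r])
      B[, cl] <- round(fm$fB[, r])
    }
  }
  ## extinct clones: closest assigned ancestor, else first assigned child
  for (cl in tum) {
    if (!anyNA(A[, cl])) next
    donors <- intersect(tree_ancestors(tree, cl), tum)
    donors <- c(donors, tree_descendants(tree, cl))
    donor <- NULL
    for (d in donors) if (!anyNA(A[, d])) { donor <- d; break }
    if (is.null(donor))
      stop("no sample-backed relative found for extinct clone ", cl)
    A[, cl] <- A[, donor]; B[, cl] <- B[, donor]
  }
  A <- cbind(A, diploid = 1); B <- cbind(B, diploid = 1)
  clone_cn_profile(A, B)
}
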