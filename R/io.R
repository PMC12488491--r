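#' Construct and validate a segment table
#'
#' Coordinates are 1-based and inclusive; `length = end - start + 1` (bp).
#' Segments must not overlap within a chromosome. Rows are sorted genomically
#' (chromosome, then start), which fixes the segment order used everywhere
#' else in the package (profile rows, run counting, CCD vectors).
#'
#' @param df data.frame with columns `segment`, `chrom`, `start`, `end` and
#'   optionally `arm`.
#' @return data.frame of class `segment_table` with an added `length` column.
#' @export
segment_table <- function(df) {
  need <- c("segment", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  df$segment <- as.character(df$segment)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (anyDuplicated(df$segment))
    stop("duplicate segment IDs: ",
         paste(unique(df$segment[duplicated(df$segment)]), collapse = ", "))
  bad <- df$start > df$end
  if (any(bad))
    stop("segment(s) with start > end: ", paste(df$segment[bad], collapse = ", "))
  chrom_lev <- unique(df$chrom[order(suppressWarnings(as.numeric(sub("^chr", "", df$chrom))),
                                     df$chrom)])
  df <- df[order(match(df$chrom, chrom_lev), df$start), , drop = FALSE]
  for (ch in chrom_lev) {
    i <- which(df$chrom == ch)
    if (length(i) > 1L && any(df$start[i][-1L] <= df$end[i][-length(i)]))
      stop("overlapping segments on chromosome ", ch)
  }
  df$length <- df$end - df$start + 1
  rownames(df) <- df$segment
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Construct and validate a clone-proportions matrix
#'
#' @param x either a long data.frame with columns `clone`, `sample`,
#'   `proportion` or a numeric matrix (clones x samples). Must include the
#'   normal clone `"diploid"`; each sample's proportions must sum to 1 within
#'   `1e-6`.
#' @param tree optional `clone_tree` for cross-validation of clone IDs.
#' @return numeric matrix (clones x samples) of class `clone_proportions`.
#' @export
clone_proportions <- function(x, tree = NULL) {
  if (is.data.frame(x)) {
    need <- c("clone", "sample", "proportion")
    if (!all(need %in% names(x)))
      stop("proportions need columns: ", paste(need, collapse = ", "))
    u <- tapply(as.numeric(x$proportion),
                list(as.character(x$clone), as.character(x$sample)), sum)
    u[is.na(u)] <- 0
  } else u <- as.matrix(x)
  if (!"diploid" %in% rownames(u))
    stop("proportions must include the normal clone 'diploid'")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    stop("clone proportions must lie in [0, 1]")
  u[u < 0] <- 0
  csum <- colSums(u)
  off <- abs(csum - 1) > 1e-6
  if (any(off))
    stop("proportions do not sum to 1 in sample(s): ",
         paste(sprintf("%s (%.4f)", colnames(u)[off], csum[off]), collapse = ", "))
  if (!is.null(tree)) {
    if (!setequal(rownames(u), tree$nodes))
      stop("clone IDs in proportions and tree differ: missing [",
           paste(setdiff(tree$nodes, rownames(u)), collapse = ", "),
           "], extra [", paste(setdiff(rownames(u), tree$nodes), collapse = ", "), "]")
    u <- u[tree$nodes, , drop = FALSE]
  }
  class(u) <- c("clone_proportions", class(u))
  u
}

#' Per-sample tumour purity
#' @param u a `clone_proportions` matrix
#' @return named vector `1 - u["diploid", ]`
#' @export
sample_purity <- function(u) 1 - u["diploid", ]

#' Validate a fractional copy-number table
#'
#' Long format: one row per (segment, sample), columns `fA`, `fA_lo`, `fA_hi`,
#' `fB`, `fB_lo`, `fB_hi`. Values are clone-proportion-weighted sums over
#' tumour clones, \eqn{f^A_{s,r} = \sum_{i\ge 1} c^A_{s,i} u_{i,r}} (the
#' diploid clone contributes nothing and no purity renormalization is
#' applied).
#'
#' @param df data.frame with columns `segment`, `sample` and the six value
#'   columns.
#' @param segments optional `segment_table` for cross-validation.
#' @return the validated data.frame, class `fractional_cn`.
#' @export
fractional_cn <- function(df, segments = NULL) {
  need <- c("segment", "sample", "fA", "fA_lo", "fA_hi", "fB", "fB_lo", "fB_hi")
  if (!all(need %in% names(df)))
    stop("fractional CN table needs columns: ", paste(need, collapse = ", "))
  df$segment <- as.character(df$segment); df$sample <- as.character(df$sample)
  for (cc in need[-(1:2)]) df[[cc]] <- as.numeric(df[[cc]])
  vals <- as.matrix(df[, need[-(1:2)]])
  if (any(vals < 0))
    stop("fractional copy numbers must be non-negative")
  for (al in c("A", "B")) {
    lo <- df[[paste0("f", al, "_lo")]]; hi <- df[[paste0("f", al, "_hi")]]
    est <- df[[paste0("f", al)]]
    bad <- lo > hi + 1e-12 | est < lo - 1e-9 | est > hi + 1e-9
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("allele %s bounds violated (lo <= estimate <= hi) for segment %s, sample %s",
                   al, df$segment[i], df$sample[i]))
    }
  }
  if (anyDuplicated(df[, c("segment", "sample")]))
    stop("duplicate (segment, sample) rows in fractional CN table")
  if (!is.null(segments)) {
    miss <- setdiff(segments$segment, df$segment)
    if (length(miss))
      stop("segments missing from fractional CN table: ",
           paste(miss, collapse = ", "))
    extra <- setdiff(df$segment, segments$segment)
    if (length(extra))
      stop("fractional CN rows for unknown segment(s): ",
           paste(extra, collapse = ", "))
  }
  class(df) <- c("fractional_cn", "data.frame")
  df
}

#' Read and cross-validate the three core inputs
#'
#' @param tree_path tree TSV (`parent`, `child`) or Newick file.
#' @param proportions_path TSV `clone  sample  proportion`.
#' @param fractional_path TSV
#'   `segment chrom start end sample fA fA_lo fA_hi fB fB_lo fB_hi`.
#' @return list with `tree`, `proportions`, `segments`, `fractional`.
#' @export
read_inputs <- function(tree_path, proportions_path, fractional_path) {
  tree <- read_tree(tree_path)
  u <- clone_proportions(utils::read.delim(proportions_path,
                                           colClasses = c(proportion = "numeric")),
                         tree = tree)
  fr_raw <- utils::read.delim(fractional_path)
  segments <- segment_table(unique(fr_raw[, c("segment", "chrom", "start", "end")]))
  fr <- fractional_cn(fr_raw, segments = segments)
  samp <- sort(unique(fr$sample))
  if (!setequal(samp, colnames(u)))
    stop("sample IDs differ between proportions [",
         paste(colnames(u), collapse = ", "), "] and fractional CN [",
         paste(samp, collapse = ", "), "]")
  list(tree = tree, proportions = u, segments = segments, fractional = fr)
}

## internal: fractional df -> list of segment x sample matrices
fractional_matrices <- function(fr, segments, samples = sort(unique(fr$sample))) {
  mk <- function(col) {
    m <- matrix(NA_real_, nrow(segments), length(samples),
                dimnames = list(segments$segment, samples))
    m[cbind(fr$segment, fr$sample)] <- fr[[col]]
    if (anyNA(m))
      stop("fractional CN table is missing (segment, sample) combinations")
    m
  }
  list(fA = mk("fA"), loA = mk("fA_lo"), hiA = mk("fA_hi"),
       fB = mk("fB"), loB = mk("fB_lo"), hiB = mk("fB_hi"))
}
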