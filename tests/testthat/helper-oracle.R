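# Independent brute-force reference for the per-segment optimization:
# exhaustively enumerates every copy-number labelling of the tumour clones,
# filters by the model constraints, and takes the lexicographic minimum of
# (objective 1, objective 2, events). Used only as a test oracle.

oracle_solve <- function(tree, u, fA, loA, hiA, fB, loB, hiB,
                         elig = NULL, cmax = 4, lambda = Inf, maxruns = 2,
                         per_allele = FALSE) {
  tum <- tumour_clones(tree)
  n <- length(tum)
  k <- length(fA)
  if (is.null(elig)) elig <- setNames(rep(FALSE, n), tum)
  nst <- (cmax + 1L)^2
  aVal <- rep(0:cmax, times = cmax + 1L)     # state index -> (a, b)
  bVal <- rep(0:cmax, each = cmax + 1L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nst)), n)))
  colnames(grid) <- tum
  A <- matrix(aVal[grid], nrow(grid), n, dimnames = list(NULL, tum))
  B <- matrix(bVal[grid], nrow(grid), n, dimnames = list(NULL, tum))
  R <- nrow(A)

  ok <- rep(TRUE, R)
  events <- rep(0L, R)
  runsA <- matrix(0L, R, n, dimnames = list(NULL, tum))
  runsB <- runsA
  signA <- runsA; signB <- runsA
  for (cl in tum) {                          # preorder: parent before child
    pa <- tree$parent[[cl]]
    pA <- if (pa == "diploid") rep(1L, R) else A[, pa]
    pB <- if (pa == "diploid") rep(1L, R) else B[, pa]
    dA <- A[, cl] - pA; dB <- B[, cl] - pB
    events <- events + abs(dA) + abs(dB)
    ok <- ok & !(pA == 0 & A[, cl] > 0) & !(pB == 0 & B[, cl] > 0)
    if (!elig[cl]) ok <- ok & !(A[, cl] == 0 & B[, cl] == 0)
    prA <- if (pa == "diploid") 0L else runsA[, pa]
    psA <- if (pa == "diploid") 0L else signA[, pa]
    prB <- if (pa == "diploid") 0L else runsB[, pa]
    psB <- if (pa == "diploid") 0L else signB[, pa]
    runsA[, cl] <- prA + (dA != 0 & sign(dA) != psA)
    signA[, cl] <- ifelse(dA != 0, sign(dA), psA)
    runsB[, cl] <- prB + (dB != 0 & sign(dB) != psB)
    signB[, cl] <- ifelse(dB != 0, sign(dB), psB)
    ok <- ok & runsA[, cl] <= maxruns & runsB[, cl] <= maxruns
  }
  ok <- ok & events <= lambda

  uT <- u[tum, , drop = FALSE]
  predA <- A %*% uT; predB <- B %*% uT      # R x k
  eps <- 1e-9
  violA <- sweep(predA, 2, loA) < -eps | sweep(predA, 2, hiA) > eps
  violB <- sweep(predB, 2, loB) < -eps | sweep(predB, 2, hiB) > eps
  obj1 <- if (per_allele) rowSums(violA) + rowSums(violB) else
    rowSums(violA | violB)
  obj2 <- rowSums(abs(sweep(predA, 2, fA))) + rowSums(abs(sweep(predB, 2, fB)))

  if (!any(ok)) stop("oracle: no feasible labelling")
  idx <- which(ok)
  o <- idx[order(obj1[idx], round(obj2[idx], 9), events[idx])]
  bi <- o[1L]
  n_opt <- sum(obj1[idx] == obj1[bi] & abs(obj2[idx] - obj2[bi]) <= 1e-9 &
                 events[idx] == events[bi])
  list(cA = setNames(A[bi, ], tum), cB = setNames(B[bi, ], tum),
       obj1 = unname(obj1[bi]), obj2 = unname(obj2[bi]),
       events = unname(events[bi]), n_optima = n_opt)
}

# naive per-position run-length SCNA counter (reference for
# count_scnas_per_edge): walks segments one by one per chromosome
oracle_count_runs <- function(delta, chrom) {
  gains <- 0L; losses <- 0L
  prev <- 0L; prev_chrom <- ""
  for (i in seq_along(delta)) {
    d <- delta[i]
    if (chrom[i] != prev_chrom) prev <- 0L
    if (d != 0 && d != prev) {
      if (d > 0) gains <- gains + 1L else losses <- losses + 1L
    }
    prev <- d; prev_chrom <- chrom[i]
  }
  c(gains = gains, losses = losses)
}

# independent checker of the path sign-run (alternation) bound
check_alternation <- function(profile, tree, maxruns = 2) {
  for (al in c("A", "B")) {
    M <- profile[[al]]
    for (cl in tumour_clones(tree)) {
      path <- rev(c(cl, setdiff(tree_ancestors(tree, cl), "diploid")))
      vals <- cbind(1, M[, path, drop = FALSE])   # diploid first
      deltas <- vals[, -1, drop = FALSE] - vals[, -ncol(vals), drop = FALSE]
      runs <- apply(deltas, 1, function(d) {
        d <- d[d != 0]
        if (!length(d)) 0L else sum(diff(c(0, sign(d))) != 0)
      })
      if (any(runs > maxruns)) return(FALSE)
    }
  }
  TRUE
}
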