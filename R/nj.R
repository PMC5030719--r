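#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration with two determinism guarantees: ties in
#' the Q matrix are broken by lexicographic taxon-pair order (each cluster
#' is keyed by its lexicographically smallest member taxon), and negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch. The final three clusters are joined in an unrooted
#' trifurcation with closed-form branch lengths
#' v_a = (d_ab + d_ac - d_bc) / 2 (and rotations).
#'
#' @param D symmetric distance matrix with zero diagonal and row names, or a
#'   `dist` object.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (is.null(rownames(D))) abort("distance matrix needs row names")
  if (nrow(D) < 3) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) abort("distance matrix diagonal must be zero")
  frags <- rownames(D)
  reps <- rownames(D)
  Dm <- D
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(Dm) > 3) {
    n <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      paste(sort(c(reps[cand[k, 1]], reps[cand[k, 2]])), collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]
    j <- pick[2]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- Dm[i, j] - li
    if (li < 0) {
      lj <- lj + li
      li <- 0
    }
    if (lj < 0) {
      li <- li + lj
      lj <- 0
    }
    frag_u <- sprintf("(%s:%s,%s:%s)", frags[i], fmt(li), frags[j], fmt(lj))
    rep_u <- min(reps[i], reps[j])
    others <- setdiff(seq_len(n), c(i, j))
    d_u <- (Dm[i, others] + Dm[j, others] - Dm[i, j]) / 2
    Dm2 <- Dm[others, others, drop = FALSE]
    Dm2 <- rbind(cbind(Dm2, d_u), c(d_u, 0))
    nn <- c(rownames(Dm)[others], rep_u)
    rownames(Dm2) <- colnames(Dm2) <- nn
    frags <- c(frags[others], frag_u)
    reps <- c(reps[others], rep_u)
    Dm <- Dm2
  }
  va <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  vb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  vc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  newick <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    frags[1], fmt(max(va, 0)), frags[2], fmt(max(vb, 0)),
    frags[3], fmt(max(vc, 0))
  )
  ape::read.tree(text = newick)
}
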