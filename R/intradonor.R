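#' Reference-anchored star alignment
#'
#' Aligns each sequence to a center sequence (ends-free) and projects it
#' onto center coordinates: insertions relative to the center are dropped,
#' deletions and unaligned flanks become gaps. This is the quick multiple
#' alignment used for intradonor chunk trees and for preparing lineage
#' members for [build_ml_tree()].
#'
#' @param seqs named character vector of sequences.
#' @param center the center (reference) sequence, e.g. the germline V.
#' @param params [align_params()].
#' @return character matrix `length(seqs)` x `nchar(center)`, rows named.
#' @export
star_align <- function(seqs, center, params = align_params()) {
  L <- nchar(center)
  out <- matrix("-", nrow = length(seqs), ncol = L,
    dimnames = list(names(seqs), NULL)
  )
  for (k in seq_along(seqs)) {
    d <- aln_detail(seqs[k], center, params, type = "overlap")
    p <- strsplit(d$pat_aln, "")[[1]]
    s <- strsplit(d$sub_aln, "")[[1]]
    pos <- d$sub_start
    for (col in seq_along(p)) {
      if (s[col] != "-") {
        pos <- pos + 1L
        if (p[col] != "-") out[k, pos] <- p[col]
      }
    }
  }
  out
}

# pairwise p-distance on a star alignment, gapped sites pairwise-deleted
star_pdist <- function(mat) {
  bin <- ape::as.DNAbin(tolower(mat))
  D <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  # pairs with no comparable sites (should not occur for reads sharing the
  # center) fall back to the maximum observed distance
  if (any(!is.finite(D))) {
    mx <- max(D[is.finite(D)], 0)
    D[!is.finite(D)] <- mx
  }
  D
}

# leaves of the minimal rooted clade containing all seed leaves; with a
# single seed this is the clade under the seed's parent node
seed_clade_tips <- function(phy, seed_labels) {
  tips <- phy$tip.label
  idx <- match(seed_labels, tips)
  if (anyNA(idx)) abort("seed leaf missing from tree")
  node <- if (length(idx) >= 2) {
    ape::getMRCA(phy, idx)
  } else {
    phy$edge[phy$edge[, 2] == idx, 1]
  }
  if (node <= length(tips)) {
    return(tips[node])
  }
  ape::extract.clade(phy, node)$tip.label
}

#' Iterative intradonor phylogenetic lineage identification
#'
#' Seeded lineage assignment by iterated neighbor-joining: surviving reads
#' are shuffled and split into chunks of at most `group_size`; each chunk is
#' aligned with the seed antibodies and the germline V (star alignment
#' around the germline), a p-distance neighbor-joining tree is built and
#' rooted on the germline leaf, and the reads inside the minimal clade
#' spanning all seeds survive into the next round. The analysis has
#' converged when at least `converge` (default 95%) of a round's input
#' survives the round.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param seeds seed antibodies (FASTA path, named vector, or tibble).
#' @param germline_v germline V gene sequence (single string; its leaf is
#'   labelled `"germline"` unless the vector is named).
#' @param group_size maximum reads per chunk (default 250).
#' @param converge convergence fraction (default 0.95).
#' @param max_iters iteration cap (default 15; a warning is issued when the
#'   cap is reached without convergence).
#' @param rng_seed integer seed for the shuffling stream (required, logged
#'   in the result).
#' @param params [align_params()].
#' @return character vector of surviving read ids; attributes `log` (per
#'   round: input, survivors) , `converged`, and `rng_seed`.
#' @export
intradonor_analysis <- function(reads, seeds, germline_v, group_size = 250,
                                converge = 0.95, max_iters = 15, rng_seed,
                                params = align_params()) {
  if (missing(rng_seed)) abort("rng_seed is required")
  seeds <- as_seed_tbl(seeds)
  if (group_size < 2 * nrow(seeds)) {
    abort("group_size must be at least twice the number of seeds")
  }
  germ_label <- names(germline_v) %||% "germline"
  germline_v <- normalize_dna(unname(germline_v), germ_label)
  reads <- as_tibble(reads)
  if (any(c(seeds$read_id, germ_label) %in% reads$read_id)) {
    abort("read ids must not collide with seed/germline labels")
  }
  surviving <- reads
  log <- list()
  sets <- list()
  converged <- FALSE
  withr::with_seed(derive_seed(rng_seed, 0L), {
    for (iter in seq_len(max_iters)) {
      n_in <- nrow(surviving)
      if (n_in == 0) break
      ord <- sample.int(n_in)
      chunks <- split(ord, ceiling(seq_along(ord) / group_size))
      keep <- character(0)
      for (ch in chunks) {
        chunk <- surviving[ch, ]
        seqs <- c(
          setNames(chunk$sequence, chunk$read_id),
          setNames(seeds$sequence, seeds$read_id),
          setNames(germline_v, germ_label)
        )
        mat <- star_align(seqs, germline_v, params)
        D <- star_pdist(mat)
        phy <- neighbor_joining(D)
        phy <- ape::root(phy, outgroup = germ_label, resolve.root = TRUE)
        clade <- seed_clade_tips(phy, seeds$read_id)
        keep <- c(keep, intersect(clade, chunk$read_id))
      }
      log[[iter]] <- tibble(
        round = iter, input = n_in, survivors = length(keep)
      )
      sets[[iter]] <- keep
      surviving <- filter(surviving, .data$read_id %in% keep)
      if (length(keep) >= converge * n_in) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged && nrow(surviving) > 0) {
    warn(sprintf(
      "intradonor analysis did not converge within %d iterations", max_iters
    ))
  }
  structure(
    surviving$read_id,
    log = bind_rows(log), sets = sets, converged = converged,
    rng_seed = rng_seed
  )
}
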