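#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ontogeny tree into a node table
#'
#' One row per node (leaves and internal nodes) with its parent, branch
#' length, type, and — for internal nodes — the inferred ancestral
#' sequence.
#'
#' @param x an `ontogeny_tree`.
#' @param ... unused.
#' @return tibble: `node`, `parent`, `branch_length`, `is_leaf`,
#'   `sequence`.
#' @method tidy ontogeny_tree
#' @export
tidy.ontogeny_tree <- function(x, ...) {
  phy <- x$tree
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  nm <- vapply(seq_len(nnode), function(v) node_name(phy, v), character(1))
  parent <- rep(NA_character_, nnode)
  blen <- rep(NA_real_, nnode)
  parent[phy$edge[, 2]] <- nm[phy$edge[, 1]]
  blen[phy$edge[, 2]] <- phy$edge.length
  seqs <- c(
    unname(x$aln[phy$tip.label]),
    unname(x$anc[phy$node.label])
  )
  tibble(
    node = nm, parent = parent, branch_length = blen,
    is_leaf = seq_len(nnode) <= ntip, sequence = seqs
  )
}

#' One-row summary of a fitted ontogeny tree
#'
#' @param x an `ontogeny_tree`.
#' @param ... unused.
#' @return tibble with `logLik`, `n_taxa`, `n_sites`, `kappa`, and the
#'   empirical base frequencies.
#' @method glance ontogeny_tree
#' @export
glance.ontogeny_tree <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    n_taxa = length(x$tree$tip.label),
    n_sites = x$n_sites,
    kappa = x$kappa,
    freq_A = x$freqs[["A"]], freq_C = x$freqs[["C"]],
    freq_G = x$freqs[["G"]], freq_T = x$freqs[["T"]]
  )
}

#' @export
print.ontogeny_tree <- function(x, ...) {
  cat(sprintf(
    "Ontogeny tree: %d leaves (germline outgroup '%s'), logLik %.3f\n",
    length(x$tree$tip.label), x$germline_id, x$loglik
  ))
  cat(sprintf(
    "HKY-type model: kappa %.2f, %d sites, %d internal ancestors\n",
    x$kappa, x$n_sites, length(x$anc)
  ))
  invisible(x)
}
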