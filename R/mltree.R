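BASES <- c("A", "C", "G", "T")

# encode an alignment (named character vector of equal-length sequences)
# into site patterns: list(states = ntaxa x npat integer matrix (0 =
# gap/ambiguous), weights, freqs, taxa, n_sites)
encode_alignment <- function(aln, freq_eps = 1e-6) {
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    abort("alignment sequences must have unique names")
  }
  L <- unique(nchar(aln))
  if (length(L) != 1) abort("sequences must be aligned (equal lengths)")
  chars <- do.call(rbind, strsplit(toupper(aln), ""))
  states <- matrix(match(chars, BASES, nomatch = 0L), nrow = length(aln))
  rownames(states) <- names(aln)
  key <- apply(states, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[uniq])))
  counts <- tabulate(states[states > 0], nbins = 4)
  freqs <- (counts + freq_eps) / sum(counts + freq_eps * 4)
  list(
    states = states[, uniq, drop = FALSE], weights = weights,
    site_pattern = match(key, key[uniq]),
    freqs = freqs, taxa = names(aln), n_sites = L
  )
}

# HKY85 rate matrix (transitions A<->G, C<->T weighted by kappa), scaled to
# one expected substitution per unit time; eigendecomposed through the
# pi-symmetrized form for fast P(t)
hky_model <- function(freqs, kappa = 2.0) {
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      ti <- (BASES[i] %in% c("A", "G")) == (BASES[j] %in% c("A", "G"))
      Q[i, j] <- freqs[j] * if (ti) kappa else 1
    }
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(
    freqs = freqs, kappa = kappa,
    vals = e$values,
    right = diag(1 / sq) %*% e$vectors,
    left = t(e$vectors) %*% diag(sq)
  )
}

pmat <- function(model, t) {
  P <- model$right %*% (exp(model$vals * t) * model$left)
  P[P < 0] <- 0
  P
}

# Felsenstein pruning log-likelihood of a (possibly multifurcating) rooted
# phylo under the HKY model; works for unrooted trees stored with a basal
# trifurcation, whose likelihood is root-invariant under reversibility.
# The hot path runs in compiled code; tree_loglik_r is the plain-R
# reference implementation kept for cross-checks.
tree_loglik <- function(phy, enc, model) {
  make_lik_fun(phy, enc, model)(NULL)
}

# fix the topology once (postorder edges, tip-state subset) and return a
# function of the edge-length vector; lik(NULL) evaluates at the tree's own
# lengths. Avoids per-evaluation subsetting in the optimizers.
make_lik_fun <- function(phy, enc, model) {
  ord <- if (identical(attr(phy, "order"), "postorder")) {
    phy
  } else {
    ape::reorder.phylo(phy, "postorder")
  }
  states <- enc$states[ord$tip.label, , drop = FALSE]
  ntip <- length(ord$tip.label)
  own <- ord$edge.length
  edge <- ord$edge
  function(el) {
    .tree_loglik_cpp(
      edge, el %||% own, ntip, states, enc$weights,
      model$freqs, model$vals, model$right, model$left
    )
  }
}

tree_loglik_r <- function(phy, enc, model) {
  states <- enc$states[phy$tip.label, , drop = FALSE]
  npat <- ncol(states)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  partial <- vector("list", nnode)
  scalelog <- 0
  ord <- ape::reorder.phylo(phy, "postorder")
  tip_partial <- function(s) {
    m <- matrix(0, 4, npat)
    known <- s > 0
    m[cbind(s[known], which(known))] <- 1
    m[, !known] <- 1
    m
  }
  for (e in seq_len(nrow(ord$edge))) {
    child <- ord$edge[e, 2]
    parent <- ord$edge[e, 1]
    cp <- if (child <= ntip) {
      tip_partial(states[child, ])
    } else {
      partial[[child]]
    }
    msg <- pmat(model, ord$edge.length[e]) %*% cp
    partial[[parent]] <- if (is.null(partial[[parent]])) {
      msg
    } else {
      partial[[parent]] * msg
    }
    if (e %% 8 == 0 && !is.null(partial[[parent]])) {
      mx <- apply(partial[[parent]], 2, max)
      mx[mx <= 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
      scalelog <- scalelog + sum(enc$weights * log(mx))
    }
  }
  root <- ord$edge[nrow(ord$edge), 1]
  site <- as.vector(model$freqs %*% partial[[root]])
  sum(enc$weights * log(site)) + scalelog
}

# optimize branch lengths one edge at a time (Brent), sweeping until the
# log-likelihood improvement falls below tol
optimize_branches <- function(phy, enc, model, sweeps = 5, tol = 1e-6,
                              upper = 5) {
  phy <- ape::reorder.phylo(phy, "postorder")
  lik <- make_lik_fun(phy, enc, model)
  el <- phy$edge.length
  ll <- lik(el)
  for (s in seq_len(sweeps)) {
    ll_before <- ll
    for (e in seq_along(el)) {
      f <- function(t) {
        el[e] <- t
        lik(el)
      }
      o <- optimize(f, c(0, upper), maximum = TRUE, tol = 1e-7)
      if (o$objective > ll) {
        el[e] <- o$maximum
        ll <- o$objective
      }
    }
    if (ll - ll_before < tol) break
  }
  phy$edge.length <- el
  list(tree = phy, loglik = ll)
}

# graft a new tip onto edge e of an unrooted tree
insert_tip <- function(phy, e, label, init_len = 0.1) {
  len <- phy$edge.length[e]
  tip <- ape::read.tree(text = sprintf("(%s:%.8f);", label, init_len))
  ape::bind.tree(phy, tip, where = phy$edge[e, 2], position = len / 2)
}

# stepwise addition under ML for one taxon order
stepwise_tree <- function(order, enc, model, init_len = 0.1) {
  first <- sprintf(
    "(%s:%.3f,%s:%.3f,%s:%.3f);",
    order[1], init_len, order[2], init_len, order[3], init_len
  )
  phy <- ape::read.tree(text = first)
  for (k in seq_along(order)[-(1:3)]) {
    cands <- list()
    lls <- numeric(0)
    for (e in seq_len(nrow(phy$edge))) {
      cand <- ape::reorder.phylo(
        insert_tip(phy, e, order[k], init_len), "postorder"
      )
      # quick scoring: optimize only the edges touching the new leaf
      tipno <- match(order[k], cand$tip.label)
      pnode <- cand$edge[cand$edge[, 2] == tipno, 1]
      touch <- which(cand$edge[, 2] == tipno | cand$edge[, 1] == pnode |
        cand$edge[, 2] == pnode)
      lik <- make_lik_fun(cand, enc, model)
      el <- cand$edge.length
      ll <- lik(el)
      for (ee in touch) {
        f <- function(t) {
          el[ee] <- t
          lik(el)
        }
        o <- optimize(f, c(0, 5), maximum = TRUE, tol = 1e-5)
        if (o$objective > ll) {
          el[ee] <- o$maximum
          ll <- o$objective
        }
      }
      cand$edge.length <- el
      cands[[length(cands) + 1]] <- cand
      lls <- c(lls, ll)
    }
    phy <- cands[[which.max(lls)]]
  }
  phy
}

# nearest-neighbor-interchange hill climbing. Neighbors are first screened
# with their inherited branch lengths (no optimization); only the
# `refine_top` best-screening candidates get full branch-length
# optimization. Returns the local optimum.
nni_search <- function(phy, enc, model, max_rounds = 30, tol = 1e-6,
                       refine_top = 8) {
  cur <- optimize_branches(phy, enc, model)
  for (r in seq_len(max_rounds)) {
    neighbors <- tryCatch(phangorn::nni(cur$tree), error = function(e) NULL)
    if (is.null(neighbors) || length(neighbors) == 0) break
    screen <- vapply(seq_along(neighbors), function(k) {
      nb <- neighbors[[k]] # [[ restores multiPhylo tip labels
      if (is.null(nb$edge.length) || anyNA(nb$edge.length)) {
        nb$edge.length <- rep(0.1, nrow(nb$edge))
      }
      tree_loglik(nb, enc, model)
    }, numeric(1))
    improved <- FALSE
    best <- cur
    for (k in utils::head(order(-screen), refine_top)) {
      nb <- neighbors[[k]]
      if (is.null(nb$edge.length) || anyNA(nb$edge.length)) {
        nb$edge.length <- rep(0.1, nrow(nb$edge))
      }
      fit <- optimize_branches(nb, enc, model, sweeps = 1)
      if (fit$loglik > best$loglik + tol) {
        best <- fit
        improved <- TRUE
      }
    }
    if (!improved) break
    cur <- best
  }
  optimize_branches(cur$tree, enc, model, sweeps = 3)
}

#' Build a maximum-likelihood ontogeny tree with ancestral sequences
#'
#' Heuristic ML tree search under an HKY-type model with empirical base
#' frequencies: for each of `n_orders` random taxon orders a
#' stepwise-addition starting tree is refined by nearest-neighbor
#' interchanges (with per-edge Brent branch-length optimization) until no
#' rearrangement improves the log-likelihood; the best of the runs is kept.
#' The tree is then rooted on the germline V outgroup and marginal
#' ancestral sequences are inferred at every internal node (per-site
#' posterior argmax; ties resolved deterministically in base order
#' A < C < G < T).
#'
#' @param aln named character vector (or `DNAStringSet`) of aligned,
#'   equal-length sequences including the germline outgroup.
#' @param germline_id name of the germline outgroup sequence.
#' @param n_orders number of random addition orders (default 3).
#' @param rng_seed integer seed for the random orders.
#' @param kappa transition/transversion ratio (default 2.0).
#' @return an object of class `ontogeny_tree`: list with `tree` (rooted
#'   `phylo`, internal nodes labelled), `anc` (named vector of ancestral
#'   sequences, one per internal node), `loglik`, `kappa`, `freqs`, `aln`.
#' @export
build_ml_tree <- function(aln, germline_id, n_orders = 3, rng_seed = 1,
                          kappa = 2.0) {
  if (inherits(aln, "DNAStringSet")) {
    aln <- setNames(as.character(aln), names(aln))
  }
  if (length(aln) < 3) abort("need at least 3 sequences")
  if (!germline_id %in% names(aln)) {
    abort(sprintf("germline '%s' not in alignment", germline_id))
  }
  enc <- encode_alignment(aln)
  model <- hky_model(enc$freqs, kappa)
  best <- NULL
  withr::with_seed(derive_seed(rng_seed, 3L), {
    for (k in seq_len(n_orders)) {
      order <- sample(enc$taxa)
      phy <- stepwise_tree(order, enc, model)
      fit <- nni_search(phy, enc, model)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  rooted <- root_on_outgroup(best$tree, germline_id)
  rooted <- label_internal(rooted)
  anc <- ancestral_sequences(rooted, enc, model)
  structure(
    list(
      tree = rooted, anc = anc, loglik = best$loglik,
      kappa = kappa, freqs = setNames(enc$freqs, BASES),
      aln = aln, n_sites = enc$n_sites, germline_id = germline_id
    ),
    class = "ontogeny_tree"
  )
}

# root an unrooted tree on the edge leading to the outgroup leaf, splitting
# that edge's length equally across the root
root_on_outgroup <- function(phy, outgroup) {
  rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  kids <- which(rooted$edge[, 1] == root)
  if (length(kids) == 2) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

label_internal <- function(phy) {
  ntip <- length(phy$tip.label)
  phy$node.label <- paste0("node", seq_len(phy$Nnode) + ntip)
  phy
}

node_name <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) phy$tip.label[node] else phy$node.label[node - ntip]
}

# marginal ancestral reconstruction: up messages by pruning, down messages
# from the root prior, per-site posterior argmax at each internal node.
# With return_posterior, also returns the normalized per-pattern posterior
# matrices (4 x npat per internal node) for validation.
ancestral_sequences <- function(phy, enc, model, return_posterior = FALSE) {
  states <- enc$states[phy$tip.label, , drop = FALSE]
  npat <- ncol(states)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ord <- ape::reorder.phylo(phy, "postorder")
  edge_len <- setNames(ord$edge.length, ord$edge[, 2])
  children <- split(ord$edge[, 2], ord$edge[, 1])
  up <- vector("list", nnode)
  msg_up <- vector("list", nnode) # message from node to its parent
  tip_partial <- function(s) {
    m <- matrix(0, 4, npat)
    known <- s > 0
    m[cbind(s[known], which(known))] <- 1
    m[, !known] <- 1
    m
  }
  for (e in seq_len(nrow(ord$edge))) {
    child <- ord$edge[e, 2]
    parent <- ord$edge[e, 1]
    cp <- if (child <= ntip) tip_partial(states[child, ]) else up[[child]]
    cp <- sweep(cp, 2, pmax(apply(cp, 2, max), 1e-300), "/")
    msg_up[[child]] <- pmat(model, ord$edge.length[e]) %*% cp
    up[[parent]] <- if (is.null(up[[parent]])) {
      msg_up[[child]]
    } else {
      up[[parent]] * msg_up[[child]]
    }
  }
  root <- ntip + 1L
  down <- vector("list", nnode)
  down[[root]] <- matrix(model$freqs, 4, npat)
  # preorder: parents before children
  pre <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]
    child <- pre[e, 2]
    if (child <= ntip) next
    above <- down[[parent]]
    for (sib in children[[as.character(parent)]]) {
      if (sib != child) above <- above * msg_up[[sib]]
    }
    d <- t(pmat(model, edge_len[[as.character(child)]])) %*% above
    down[[child]] <- sweep(d, 2, pmax(apply(d, 2, max), 1e-300), "/")
  }
  pat_of_site <- enc$site_pattern
  out <- character(phy$Nnode)
  names(out) <- phy$node.label
  posts <- if (return_posterior) {
    setNames(vector("list", phy$Nnode), phy$node.label)
  }
  for (v in (ntip + 1L):nnode) {
    post <- up[[v]] * down[[v]]
    states_v <- apply(post, 2, which.max)
    out[v - ntip] <- paste(BASES[states_v][pat_of_site], collapse = "")
    if (return_posterior) {
      posts[[v - ntip]] <- sweep(post, 2, colSums(post), "/")
    }
  }
  if (return_posterior) {
    return(list(seqs = out, posterior = posts, pat_of_site = pat_of_site))
  }
  out
}
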