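fix_hky_case <- function(seed, ntaxa = 5, n_sites = 600) {
  withr::with_seed(seed, {
    tr <- ape::rtree(ntaxa, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
    model <- ontorep:::hky_model(c(0.3, 0.2, 0.25, 0.25), 2)
    aln <- sim_hky_aln(tr, model, n_sites)
    list(tree = tr, aln = aln)
  })
}

test_that("HKY log-likelihood matches phangorn and the plain-R reference", {
  for (seed in c(71, 72, 73)) {
    case <- fix_hky_case(seed)
    enc <- ontorep:::encode_alignment(case$aln)
    model <- ontorep:::hky_model(enc$freqs, 2)
    ll <- ontorep:::tree_loglik(case$tree, enc, model)
    expect_equal(ll, ontorep:::tree_loglik_r(case$tree, enc, model),
      tolerance = 1e-9
    )
    dat <- phangorn::phyDat(t(sapply(strsplit(case$aln, ""), identity)))
    fit <- phangorn::pml(case$tree, dat, bf = enc$freqs, Q = c(1, 2, 1, 1, 2, 1))
    expect_equal(ll, fit$logLik, tolerance = 1e-6)
  }
})

test_that("branch optimization never decreases the log-likelihood", {
  case <- fix_hky_case(74)
  enc <- ontorep:::encode_alignment(case$aln)
  model <- ontorep:::hky_model(enc$freqs, 2)
  start <- case$tree
  start$edge.length <- rep(0.2, nrow(start$edge))
  ll0 <- ontorep:::tree_loglik(start, enc, model)
  fit <- ontorep:::optimize_branches(start, enc, model)
  expect_gte(fit$loglik, ll0)
  fit2 <- ontorep:::nni_search(start, enc, model)
  expect_gte(fit2$loglik, fit$loglik - 1e-6)
})

test_that("search matches exhaustive enumeration on small alignments", {
  for (seed in c(75, 76, 77)) {
    case <- fix_hky_case(seed)
    enc <- ontorep:::encode_alignment(case$aln)
    model <- ontorep:::hky_model(enc$freqs, 2)
    res <- build_ml_tree(case$aln, names(case$aln)[1], rng_seed = seed)
    alltr <- phangorn::allTrees(5, rooted = FALSE, tip.label = names(case$aln))
    lls <- vapply(seq_along(alltr), function(k) {
      tt <- alltr[[k]]
      tt$edge.length <- rep(0.1, nrow(tt$edge))
      ontorep:::optimize_branches(tt, enc, model, sweeps = 4)$loglik
    }, numeric(1))
    expect_equal(
      as.numeric(ape::dist.topo(ape::unroot(res$tree), alltr[[which.max(lls)]])),
      0
    )
    expect_gte(res$loglik, max(lls) - 1e-3)
  }
})

test_that("identical sequences give zero branch lengths and trivial ancestors", {
  s <- rand_dna(300)
  aln <- setNames(rep(s, 4), c("germ", "a", "b", "c"))
  res <- build_ml_tree(aln, "germ", rng_seed = 1)
  expect_lt(max(res$tree$edge.length), 1e-4)
  expect_true(all(res$anc == s))
})

test_that("marginal ancestral posteriors match brute-force enumeration", {
  withr::local_seed(78)
  # 3 leaves rooted on the germline edge -> 2 internal nodes to marginalize
  aln <- setNames(
    c(rand_dna(120), rand_dna(120), rand_dna(120)),
    c("g", "a", "b")
  )
  res <- build_ml_tree(aln, "g", rng_seed = 1)
  phy <- res$tree
  enc <- ontorep:::encode_alignment(aln)
  model <- ontorep:::hky_model(enc$freqs, res$kappa)
  rec <- ontorep:::ancestral_sequences(phy, enc, model, return_posterior = TRUE)
  # brute force over joint states of the internal nodes
  ntip <- 3L
  states <- enc$states[phy$tip.label, , drop = FALSE]
  edges <- phy$edge
  elen <- phy$edge.length
  P <- lapply(seq_len(nrow(edges)), function(e) ontorep:::pmat(model, elen[e]))
  nodes <- sort(unique(edges[, 1]))
  for (pat in seq_len(ncol(states))) {
    joint <- array(0, dim = rep(4, length(nodes)))
    idx <- as.matrix(expand.grid(rep(list(1:4), length(nodes))))
    for (r in seq_len(nrow(idx))) {
      assign_state <- function(v) {
        if (v <= ntip) states[v, pat] else idx[r, match(v, nodes)]
      }
      pr <- model$freqs[idx[r, match(ntip + 1L, nodes)]]
      for (e in seq_len(nrow(edges))) {
        sv <- assign_state(edges[e, 2])
        pv <- assign_state(edges[e, 1])
        pr <- pr * if (sv == 0) 1 else P[[e]][pv, sv]
      }
      joint[matrix(idx[r, ], 1)] <- joint[matrix(idx[r, ], 1)] + pr
    }
    for (v in nodes) {
      marg <- apply(joint, match(v, nodes), sum)
      marg <- marg / sum(marg)
      nm <- ontorep:::node_name(phy, v)
      expect_equal(rec$posterior[[nm]][, pat], unname(marg), tolerance = 1e-9)
    }
  }
})

test_that("tidy and glance summarize the fitted tree", {
  case <- fix_hky_case(79)
  res <- build_ml_tree(case$aln, names(case$aln)[1], rng_seed = 2)
  td <- tidy(res)
  expect_equal(nrow(td), length(res$tree$tip.label) + res$tree$Nnode)
  expect_equal(sum(is.na(td$parent)), 1) # only the root has no parent
  expect_true(all(nchar(td$sequence) == res$n_sites))
  gl <- glance(res)
  expect_equal(gl$logLik, res$loglik)
  expect_equal(gl$n_taxa, 5)
})
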