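# shared fixtures, built once per test run and memoized

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

fix_cfg <- function() {
  sim_config(
    rng_seed = 101, n_lineages = 1, lineage_sizes = c(6, 6, 6),
    n_background = c(15, 15, 15), shm_rate = 0.04
  )
}

fix_sim <- function() memo("sim", simulate_repertoire(fix_cfg()))

fix_lib <- function() fix_sim()$lib

fix_master <- function() {
  memo("master", annotate_reads(fix_sim()$reads, fix_lib()))
}

# Biostrings pairwise alignment oracle (independent of the native engine)
oracle_aln <- function(a, b, type = "local", p = align_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = p$match, mismatch = p$mismatch, baseOnly = FALSE
  )
  mat["N", ] <- 0
  mat[, "N"] <- 0
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = type, substitutionMatrix = mat,
    gapOpening = p$gap_open, gapExtension = p$gap_extend
  )
}

oracle_score <- function(a, b, type = "local", p = align_params()) {
  Biostrings::score(oracle_aln(a, b, type, p))
}

oracle_identity <- function(a, b, p = align_params()) {
  aln <- oracle_aln(a, b, "global", p)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# simulate sequences under the package's own HKY model along a tree
sim_hky_aln <- function(phy, model, n_sites) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntip <- length(phy$tip.label)
  seqs <- vector("list", ntip + phy$Nnode)
  seqs[[ntip + 1L]] <- sample(1:4, n_sites, TRUE, prob = model$freqs)
  for (e in seq_len(nrow(phy$edge))) {
    P <- ontorep:::pmat(model, phy$edge.length[e])
    parent <- seqs[[phy$edge[e, 1]]]
    seqs[[phy$edge[e, 2]]] <- vapply(
      parent, function(s) sample(1:4, 1, prob = P[s, ]), integer(1)
    )
  }
  setNames(
    vapply(seq_len(ntip), function(i) {
      paste(c("A", "C", "G", "T")[seqs[[i]]], collapse = "")
    }, character(1)),
    phy$tip.label
  )
}

# write a small germline FASTA and return its path
write_tmp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  write_fasta(seqs, path)
  path
}
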