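test_that("time-point merging collapses identical sequences with birthdays", {
  dir <- withr::local_tempdir()
  shared <- rand_dna(100)
  only34 <- rand_dna(100)
  only59 <- rand_dna(100)
  write_fasta(c(s1 = shared, u1 = only34), file.path(dir, "wk34.fasta"))
  write_fasta(c(s2 = shared, u2 = only59), file.path(dir, "wk59.fasta"))
  merged <- merge_timepoints(
    file.path(dir, c("wk34.fasta", "wk59.fasta")),
    c("wk34", "wk59")
  )
  expect_equal(nrow(merged), 3)
  expect_equal(sum(merged$copies), 4) # conservation
  sh <- merged[merged$sequence == shared, ]
  expect_equal(sh$birthday, "wk34")
  expect_equal(sh$seq_id, "wk34-s1")
  expect_equal(sh$observed_at[[1]], c("wk34", "wk59"))
  expect_equal(sh$copies, 2)
  expect_equal(merged$birthday[merged$sequence == only59], "wk59")
})

test_that("merging rejects duplicate ids within a file", {
  dir <- withr::local_tempdir()
  writeLines(c(">a", "ACGT", ">a", "ACGG"), file.path(dir, "x.fasta"))
  expect_error(
    merge_timepoints(file.path(dir, "x.fasta"), "t0"),
    "duplicate"
  )
  expect_error(
    merge_timepoints(file.path(dir, "x.fasta"), c("t0", "t0")),
    "length"
  )
})

test_that("simulated birthdays equal first-emergence labels", {
  cfg <- sim_config(
    rng_seed = 81, n_lineages = 1, lineage_sizes = c(6, 6, 6),
    n_background = c(3, 3, 3), carryover_prob = 0.5
  )
  sim <- simulate_repertoire(cfg)
  dir <- withr::local_tempdir()
  paths <- write_repertoire(sim, dir)
  merged <- merge_timepoints(unname(paths), cfg$timepoints)
  truth_first <- sim$truth |>
    dplyr::distinct(.data$sequence, .data$first_timepoint)
  cmp <- dplyr::left_join(merged, truth_first, by = "sequence")
  expect_equal(cmp$birthday, cmp$first_timepoint)
  expect_equal(sum(merged$copies), nrow(sim$reads))
})

# hand-built ontogeny object whose UCA-to-target path has cumulative
# amino-acid changes 0, 2, 5, 8, 12 (one A -> P change per mutated codon)
chain_fixture <- function() {
  base <- strrep("GCT", 20)
  mutn <- function(k) {
    paste0(strrep("CCT", k), substr(base, 3 * k + 1, nchar(base)))
  }
  nwk <- "(((((target:1,o4:1)n4:1,o3:1)n3:1,o2:1)n2:1,o1:1)n1:1,germ:1)root;"
  phy <- ape::read.tree(text = nwk)
  anc <- setNames(rep(base, phy$Nnode), phy$node.label)
  anc["n1"] <- mutn(0)
  anc["n2"] <- mutn(2)
  anc["n3"] <- mutn(5)
  anc["n4"] <- mutn(8)
  aln <- setNames(
    c(mutn(12), rep(base, 4), base),
    c("target", "o1", "o2", "o3", "o4", "germ")
  )
  structure(
    list(
      tree = phy, anc = anc, aln = aln, loglik = 0, kappa = 2,
      freqs = c(A = .25, C = .25, G = .25, T = .25),
      n_sites = nchar(base), germline_id = "germ"
    ),
    class = "ontogeny_tree"
  )
}

test_that("intermediate picking hits the evenly spaced targets", {
  x <- chain_fixture()
  phy <- x$tree
  uca <- ontorep:::uca_node(phy, "germ")
  expect_equal(ontorep:::node_name(phy, uca), "n1")
  # n = 3 with total 12: targets 3, 6, 9 -> nearest cum values 2, 5, 8
  ints <- pick_intermediates(x, "target", n = 3)
  expect_equal(ints$node, c("n1", "n2", "n3", "n4"))
  expect_equal(ints$cum_aa, c(0, 2, 5, 8))
  expect_true(!is.unsorted(ints$cum_aa)) # ordered along the path
  # spacing mode: emit whenever >= 3 aa accumulated since the last pick
  ints2 <- pick_intermediates(x, "target", spacing_aa = 3)
  expect_equal(ints2$node, c("n1", "n3", "n4", "target"))
  expect_true(all(diff(ints2$cum_aa) >= 3))
  expect_error(pick_intermediates(x, "target"), "exactly one")
  expect_error(pick_intermediates(x, "nope", n = 1), "not a leaf")
})

test_that("a path with no changes returns only the UCA", {
  s <- strrep("GCT", 10)
  nwk <- "((a:1,(b:1,c:1)n2:1)n1:1,germ:1)root;"
  phy <- ape::read.tree(text = nwk)
  x <- structure(
    list(
      tree = phy,
      anc = setNames(rep(s, 3), c("root", "n1", "n2")),
      aln = setNames(rep(s, 4), c("a", "b", "c", "germ")),
      loglik = 0, kappa = 2, freqs = c(A = 1, C = 0, G = 0, T = 0) / 1,
      n_sites = nchar(s), germline_id = "germ"
    ),
    class = "ontogeny_tree"
  )
  ints <- pick_intermediates(x, "b", n = 2)
  expect_equal(ints$node, "n1")
  expect_equal(ints$cum_aa, 0)
  mr <- lineage_mrca(x, c("b", "c"))
  expect_equal(mr$node, "n2")
  expect_equal(mr$sequence, s)
})

test_that("minor-branch collapsing honours size and keep rules", {
  # 10 leaves sharing a CDR3 under one clade
  tips <- sprintf("L%02d", 1:10)
  nwk <- sprintf(
    "((%s)cladeA:1,germ:1)root;",
    paste(sprintf("%s:0.1", tips), collapse = ",")
  )
  phy <- ape::read.tree(text = nwk)
  cdr3 <- setNames(rep("GCGAGAGATTTT", 10), tips)
  col <- collapse_minor_branches(
    phy, cdr3,
    identity = 0.9, min_size = 3, keep = "germ"
  )
  expect_equal(nrow(col$summary), 1)
  expect_equal(col$summary$size, 10)
  expect_equal(col$summary$representative_cdr3, "GCGAGAGATTTT")
  expect_setequal(col$tree$tip.label, c(col$summary$branch_id, "germ"))

  # a kept mAb inside a small clade survives while its sibling is pruned
  nwk2 <- "(((mab1:1,x1:1)a:1,(y1:0.1,y2:0.1,y3:0.1,y4:0.1,y5:0.1)b:1)u:1,germ:1)root;"
  phy2 <- ape::read.tree(text = nwk2)
  cdr32 <- setNames(
    c("AAAAAACCCCCC", rep("GGGGGGTTTTTT", 5)),
    c("x1", paste0("y", 1:5))
  )
  col2 <- collapse_minor_branches(
    phy2, cdr32,
    identity = 0.9, min_size = 5, keep = c("mab1", "germ")
  )
  expect_true("mab1" %in% col2$tree$tip.label)
  expect_false("x1" %in% col2$tree$tip.label)
  expect_equal(col2$summary$size, 5)
  expect_equal(attr(col2, "n_pruned"), 1)
})

test_that("collapsing recovers planted CDR3 clades and conserves leaves", {
  withr::local_seed(82)
  sizes <- c(8, 6, 2)
  junctions <- replicate(3, rand_dna(30))
  tips <- list()
  sub <- character(0)
  for (g in 1:3) {
    ids <- sprintf("g%d_%d", g, seq_len(sizes[g]))
    tips[[g]] <- ids
    sub <- c(sub, sprintf(
      "(%s)c%d:1",
      paste(sprintf("%s:0.05", ids), collapse = ","), g
    ))
  }
  nwk <- sprintf("((%s)u:1,germ:1)root;", paste(sub, collapse = ","))
  phy <- ape::read.tree(text = nwk)
  cdr3 <- setNames(
    rep(junctions, times = sizes),
    unlist(tips)
  )
  col <- collapse_minor_branches(
    phy, cdr3,
    identity = 0.85, min_size = 5, keep = "germ"
  )
  expect_equal(nrow(col$summary), 2)
  expect_setequal(col$summary$size, c(8, 6))
  expect_equal(
    sum(col$summary$size) + attr(col, "n_pruned"),
    sum(sizes)
  )
})

test_that("partition arithmetic and NEXUS round-trip", {
  region_map <- c(
    rep("FWR1", 6), rep("CDR1", 6), rep("FWR2", 3),
    rep("CDR2", 3), rep("FWR3", 3), rep("CDR3", 6)
  )
  parts <- partition_alignment(27, region_map)
  expect_equal(length(parts$pos12), 18)
  expect_equal(length(parts$pos3), 9)
  # exact cover, pairwise disjoint
  expect_setequal(c(parts$cdr, parts$fwr), parts$vdj)
  expect_length(intersect(parts$cdr, parts$fwr), 0)
  expect_setequal(c(parts$pos12, parts$pos3), parts$vdj)
  expect_length(intersect(parts$pos12, parts$pos3), 0)
  path <- file.path(withr::local_tempdir(), "sets.nex")
  write_nexus_sets(parts, path)
  rt <- read_nexus_sets(path)
  expect_equal(
    lapply(parts, as.integer),
    lapply(rt, as.integer)
  )
  # junction alias and validation
  expect_silent(partition_alignment(3, rep("junction", 3)))
  expect_error(partition_alignment(3, rep("V", 3)), "unknown")
  expect_error(partition_alignment(4, rep("CDR1", 4)), "divisible")
  expect_error(partition_alignment(6, rep("CDR1", 3)), "every")
})
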