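test_that("id-div table: germline copy has divergence 0, self-seed identity 100", {
  lib <- fix_lib()
  v <- lib[lib$segment == "V", ][1, ]
  j <- lib[lib$segment == "J", ][1, ]
  read <- paste0(v$sequence, "GCTGCTGCT", j$sequence)
  m <- annotate_reads(tibble::tibble(read_id = "r1", sequence = read), lib)
  seeds <- tibble::tibble(read_id = "seed1", sequence = read)
  rec <- calc_id_div(m, seeds, lib)
  expect_equal(rec$divergence, 0)
  expect_equal(rec$seed1, 100)
  expect_equal(rec$v_gene, v$gene_name)
})

test_that("divergence arithmetic: substitutions over aligned columns", {
  # dedicated 300-nt V allele so the percentage is exact
  dir <- withr::local_tempdir()
  vseq <- withr::with_seed(51, paste0(
    ontorep:::sample_codons(88, exclude = ontorep:::STOP_CODONS),
    ontorep:::sample_codons(10, exclude = c(ontorep:::STOP_CODONS, "TGT", "TGC")),
    "TGT", "GCG"
  ))
  expect_equal(nchar(vseq), 300)
  writeLines(c(">VX1-1*01", vseq), file.path(dir, "v.fasta"))
  lib <- annotate_anchors(
    load_germline_library(file.path(dir, "v.fasta"), "V", "heavy")
  )
  # substitutions kept away from the alignment ends so the local hit spans
  # the whole reference and the denominator is exactly 300
  withr::local_seed(52)
  read <- mutate_positions(vseq, sample(10:250, 12))
  m <- annotate_reads(
    tibble::tibble(read_id = "r", sequence = read),
    dplyr::bind_rows(lib, fix_lib()[fix_lib()$segment == "J", ])
  )
  rec <- suppressMessages(calc_id_div(
    m, tibble::tibble(read_id = "s", sequence = vseq), lib
  ))
  expect_equal(rec$divergence, 100 * 12 / 300, tolerance = 1e-9)
})

test_that("island extraction uses closed bounds", {
  rec <- tibble::tibble(
    read_id = c("a", "b", "c"),
    v_gene = "IGHV1-1",
    divergence = c(4, 10, 50),
    mab1 = c(90, 85, 60)
  )
  isl <- island("mab1", min_identity = 85)
  expect_setequal(get_island(rec, isl), c("a", "b"))
  isl2 <- island("mab1", min_identity = 85, max_divergence = 5)
  expect_equal(get_island(rec, isl2), "a")
  expect_error(get_island(rec, island("nope", 80)), "unknown seed")
})

test_that("CDR3 lineage clustering groups by gene before clustering", {
  base <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    v_gene = c("IGHV1-1", "IGHV1-1", "IGHV2-2"),
    j_gene = "IGHJ1-1",
    cdr3_nt = rep("GCGAGAGATTTT", 3)
  )
  lin <- cluster_cdr3_lineages(base)
  expect_equal(nrow(lin), 2)
  expect_equal(sum(lin$size), 3)
  # same V/J and identical CDR3: one lineage
  one <- lin[lin$v_gene == "IGHV1-1", ]
  expect_equal(one$size, 2)
  expect_setequal(one$member_ids[[1]], c("r1", "r2"))
})

test_that("planted lineages are recovered exactly (ARI 1)", {
  withr::local_seed(53)
  junctions <- replicate(3, rand_dna(36))
  rows <- list()
  for (g in 1:3) {
    for (i in 1:8) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        read_id = sprintf("g%d_%d", g, i),
        v_gene = "IGHV1-1", j_gene = "IGHJ1-1",
        cdr3_nt = mutate_positions(junctions[g], sample(36, 1)),
        truth = g
      )
    }
  }
  x <- dplyr::bind_rows(rows)
  lin <- cluster_cdr3_lineages(x, identity = 0.85)
  expect_equal(nrow(lin), 3)
  assign <- integer(nrow(x))
  for (i in seq_len(nrow(lin))) {
    assign[match(lin$member_ids[[i]], x$read_id)] <- i
  }
  expect_equal(mclust::adjustedRandIndex(assign, x$truth), 1)
})

test_that("seeds participate in clustering and flag their lineage", {
  x <- tibble::tibble(
    read_id = c("r1", "r2"),
    v_gene = "IGHV1-1", j_gene = "IGHJ1-1",
    cdr3_nt = c("GCGAGAGATTTT", "TTTTAAACCCGG")
  )
  seeds <- tibble::tibble(
    read_id = "mab1",
    v_gene = "IGHV1-1", j_gene = "IGHJ1-1",
    cdr3_nt = "GCGAGAGATTTT"
  )
  lin <- cluster_cdr3_lineages(x, seeds = seeds)
  seeded <- lin[lin$seeded, ]
  expect_equal(nrow(seeded), 1)
  expect_true("r1" %in% seeded$member_ids[[1]])
  expect_equal(seeded$seed_names[[1]], "mab1")
  expect_false(any(lin$seeded[!vapply(lin$member_ids, function(m) "mab1" %in% m, logical(1))]))
})

test_that("lineage output partitions the CDR3-bearing reads", {
  m <- fix_master()
  lin <- suppressMessages(cluster_cdr3_lineages(m))
  members <- unlist(lin$member_ids)
  expect_equal(sort(members), sort(m$read_id[!is.na(m$cdr3_nt) &
    !is.na(m$v_gene) & !is.na(m$j_gene)]))
  expect_equal(sum(lin$size), length(members))
})
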