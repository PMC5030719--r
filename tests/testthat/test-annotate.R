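test_that("length filtering is inclusive and logged", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    sequence = c(rand_dna(150), rand_dna(400), rand_dna(700), rand_dna(300))
  )
  kept <- filter_by_length(reads)
  expect_setequal(kept$read_id, c("b", "d"))
  disc <- attr(kept, "discarded")
  expect_setequal(disc$read_id, c("a", "c"))
  expect_true(all(disc$status == "wrong_length"))
  expect_equal(nrow(filter_by_length(reads[0, ])), 0)
})

test_that("V assignment: identity, mutation, reverse strand, absence", {
  lib <- fix_lib()
  vlib <- lib[lib$segment == "V", ]
  allele <- vlib[1, ]
  # exact germline copy
  hit <- assign_v(allele$sequence, lib)
  expect_equal(hit$gene_name, allele$gene_name)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$strand, "+")
  # 15 substitutions over the V: same gene, mismatch count agrees with the
  # Biostrings oracle
  withr::local_seed(21)
  mut <- mutate_positions(allele$sequence, sample(nchar(allele$sequence), 15))
  hit2 <- assign_v(mut, lib)
  expect_equal(hit2$gene_name, allele$gene_name)
  oa <- oracle_aln(mut, allele$sequence, "local")
  expect_equal(hit2$mismatches, Biostrings::nmismatch(oa))
  # reverse-complement input is recognized on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  hit3 <- assign_v(rc, lib)
  expect_equal(hit3$gene_name, allele$gene_name)
  expect_equal(hit3$strand, "-")
  # random non-Ig sequence has no acceptable hit
  expect_null(assign_v(rand_dna(400), lib))
})

test_that("J assignment scans only downstream of the V match", {
  lib <- fix_lib()
  v <- lib[lib$segment == "V", ][1, ]
  j <- lib[lib$segment == "J", ][1, ]
  read <- paste0(v$sequence, "GCGAGAGATTTT", j$sequence)
  v_hit <- assign_v(read, lib)
  j_hit <- assign_j(read, v_hit, lib)
  expect_equal(j_hit$gene_name, j$gene_name)
  expect_gte(j_hit$read_start, v_hit$read_end)
  # truncated before J: absent
  trunc <- substr(read, 1, v_hit$read_end + 4)
  expect_null(assign_j(trunc, assign_v(trunc, lib), lib))
})

test_that("D and C are searched only in their own windows", {
  lib <- fix_lib()
  v <- lib[lib$segment == "V", ][1, ]
  d <- lib[lib$segment == "D", ][1, ]
  j <- lib[lib$segment == "J", ][1, ]
  cseg <- lib[lib$segment == "C", ][1, ]
  read <- paste0(
    v$sequence, "AAT", substr(d$sequence, 1, 15), "TTA", j$sequence,
    substr(cseg$sequence, 1, 40)
  )
  v_hit <- assign_v(read, lib)
  j_hit <- assign_j(read, v_hit, lib)
  dc <- assign_d_and_c(read, v_hit, j_hit, lib)
  expect_equal(dc$d$gene_name, d$gene_name)
  expect_equal(dc$c$gene_name, cseg$gene_name)
  # a 4-nt junction cannot host a D call
  read2 <- paste0(v$sequence, "AATT", j$sequence)
  v2 <- assign_v(read2, lib)
  j2 <- assign_j(read2, v2, lib)
  dc2 <- assign_d_and_c(read2, v2, j2, lib)
  expect_null(dc2$d)
  # both searches can be disabled
  dc3 <- assign_d_and_c(read, v_hit, j_hit, lib, do_d = FALSE, do_c = FALSE)
  expect_null(dc3$d)
  expect_null(dc3$c)
})

test_that("CDR3 extraction maps anchors into read coordinates", {
  lib <- fix_lib()
  v <- lib[lib$segment == "V", ][1, ]
  j <- lib[lib$segment == "J", ][1, ]
  # junction built so the CDR3 is exactly the V tail + insert + J head
  insert <- "GCGAGAGATTTTTGG"
  v_trunc <- substr(v$sequence, 1, v$anchor + 3) # end exactly at the Cys codon
  j_full <- j$sequence
  read <- paste0(v_trunc, insert, "", substr(j_full, 1, nchar(j_full)))
  # expected CDR3: insert plus the J head before the anchor
  expected <- paste0(insert, substr(j_full, 1, j$anchor))
  v_hit <- assign_v(read, lib)
  j_hit <- assign_j(read, v_hit, lib)
  cdr3 <- extract_cdr3(read, v_hit, j_hit, lib)
  expect_equal(cdr3$cdr3_nt, expected)
  if (nchar(expected) %% 3 == 0) {
    expect_equal(cdr3$cdr3_aa, translate_nt(expected))
  }
})

test_that("status precedence: indel, stop, good", {
  lib <- fix_lib()
  base <- fix_master()
  base <- base$sequence[base$status == "good"][1]
  # one deleted nucleotide inside the V: indel
  del <- paste0(substr(base, 1, 99), substr(base, 101, nchar(base)))
  reads <- tibble::tibble(
    read_id = c("clean", "del"),
    sequence = c(base, del)
  )
  m <- annotate_reads(reads, lib)
  expect_equal(m$status[m$read_id == "clean"], "good")
  expect_equal(m$status[m$read_id == "del"], "indel")
  # in-frame TAA in the junction: stop
  v <- lib[lib$segment == "V", ][1, ]
  j <- lib[lib$segment == "J", ][1, ]
  v_trunc <- substr(v$sequence, 1, v$anchor + 3)
  head_len <- j$anchor
  pad <- (3 - (6 + head_len) %% 3) %% 3
  stop_read <- paste0(v_trunc, "GCGTAA", strrep("A", pad), j$sequence)
  m2 <- annotate_reads(
    tibble::tibble(read_id = "s", sequence = stop_read), lib
  )
  expect_equal(m2$status, "stop")
})

test_that("every read gets exactly one status and counts are conserved", {
  m <- fix_master()
  sim <- fix_sim()
  expect_equal(nrow(m), nrow(sim$reads))
  expect_false(any(is.na(m$status)))
  expect_true(all(m$status %in% ontorep:::READ_STATUSES))
  expect_equal(sum(table(m$status)), nrow(sim$reads))
  # master invariants from the type contract
  with_v <- !is.na(m$v_allele)
  expect_true(all(is.na(m$status) | m$status != "no_V" | !with_v))
  good <- m$status %in% c("good", "unique", "indel", "stop")
  expect_true(all(!good | (with_v & !is.na(m$j_allele))))
})

test_that("annotation recovers simulated truth on a small batch", {
  m <- fix_master()
  sim <- fix_sim()
  j <- dplyr::left_join(
    tibble::as_tibble(m), sim$truth,
    by = "read_id", suffix = c("", ".t")
  )
  expect_gte(mean(j$v_gene == sub("\\*.*$", "", j$v_allele.t), na.rm = FALSE), 0.95)
  expect_gte(mean(j$j_gene == sub("\\*.*$", "", j$j_allele.t)), 0.95)
  expect_gte(mean(!is.na(j$cdr3_nt) & j$cdr3_nt == j$junction_nt), 0.9)
})

test_that("annotation outputs write master table, usage tables and subsets", {
  m <- fix_master()
  dir <- withr::local_tempdir()
  write_annotation(m, dir)
  master <- readr::read_tsv(
    file.path(dir, "tables", "master.tsv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(master), nrow(m))
  expect_true(all(c("read_id", "v_gene", "cdr3_aa", "status") %in% names(master)))
  expect_true(file.exists(file.path(dir, "tables", "v_usage.tsv")))
  fa <- read_seqs(file.path(dir, "sequences", "goodCDR3.fasta"))
  expect_equal(nrow(fa), sum(m$status == "good"))
})
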