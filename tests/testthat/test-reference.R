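test_that("germline loading parses headers, collapses alleles, groups duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "v.fasta")
  shared <- rand_dna(60)
  writeLines(c(
    ">IGHV3-30*18", shared,
    ">IGHV3-30-5*01", shared,
    ">X123|IGHV1-2*02|Homo sapiens|F|V-REGION|1..60|60 nt|", rand_dna(60),
    ">X124|IGHV9-9*01|Homo sapiens|ORF|V-REGION|1..60|60 nt|", rand_dna(60)
  ), path)
  lib <- load_germline_library(path, "V", "heavy")
  expect_equal(sort(lib$gene_name), sort(c("IGHV3-30", "IGHV3-30-5", "IGHV1-2")))
  expect_true(all(!grepl("\\*", lib$gene_name)))
  expect_true(all(startsWith(lib$allele_name, lib$gene_name)))
  # ORF excluded by default, retained on request
  expect_false("IGHV9-9*01" %in% lib$allele_name)
  lib2 <- load_germline_library(path, "V", "heavy", keep_orf_p = TRUE)
  expect_true("IGHV9-9*01" %in% lib2$allele_name)
  # identically sequenced alleles share one duplicate group
  grps <- duplicate_groups(lib)
  pair <- grps[vapply(grps, function(g) "IGHV3-30*18" %in% g, logical(1))][[1]]
  expect_setequal(pair, c("IGHV3-30*18", "IGHV3-30-5*01"))
  # every allele in exactly one group
  expect_setequal(unlist(grps), lib$allele_name)
})

test_that("loader rejects bad inputs with named errors", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "conflict.fasta")
  writeLines(c(">X*01", "ACGT", ">X*01", "ACGG"), p1)
  expect_error(load_germline_library(p1, "V", "heavy"), "X\\*01")
  p2 <- file.path(dir, "empty.fasta")
  writeLines(character(0), p2)
  expect_error(load_germline_library(p2, "V", "heavy"), "empty")
  p3 <- file.path(dir, "badchar.fasta")
  writeLines(c(">OK*01", "ACGT", ">BAD*01", "ACQT"), p3)
  expect_error(load_germline_library(p3, "V", "heavy"), "BAD\\*01")
  expect_error(load_germline_library(file.path(dir, "nope.fa"), "V", "heavy"))
})

test_that("sequences are normalized: case, RNA, gaps", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "norm.fasta")
  writeLines(c(">A*01", "acgu-ac.gt"), p)
  lib <- load_germline_library(p, "V", "heavy")
  expect_equal(lib$sequence, "ACGTACGT")
})

test_that("anchor annotation finds Cys-104 and W/F-G-X-G motifs", {
  # V: single in-frame TGT near the end
  v <- paste0(strrep("GCA", 30), "TGT", "GCGAGAGA")
  # J: W-G-Q-G motif after an 18-nt head
  j <- paste0("AAACCCTTTAAACCCTTT", "TGGGGCCAAGGG", strrep("ACA", 4))
  j_none <- strrep("ACA", 16)
  lib <- tibble::tibble(
    allele_name = c("V1*01", "J1*01", "J2*01"),
    gene_name = c("V1", "J1", "J2"),
    segment = c("V", "J", "J"),
    chain = "heavy",
    sequence = c(v, j, j_none),
    functionality = "F",
    duplicate_group = 1:3,
    anchor = NA_integer_, unanchored = NA
  )
  class(lib) <- c("germline_library", class(lib))
  lib <- annotate_anchors(lib)
  expect_equal(lib$anchor[lib$allele_name == "V1*01"], 90L)
  expect_equal(substr(v, 91, 93), "TGT")
  expect_equal(lib$anchor[lib$allele_name == "J1*01"], 18L)
  expect_true(lib$unanchored[lib$allele_name == "J2*01"])
  expect_false(any(lib$unanchored[lib$allele_name != "J2*01"]))
})

test_that("library round-trips through FASTA", {
  lib <- fix_lib()
  vlib <- lib[lib$segment == "V", ]
  dir <- withr::local_tempdir()
  path <- file.path(dir, "IGHV.fasta")
  write_germline_library(vlib, path)
  re <- annotate_anchors(load_germline_library(path, "V", "heavy"))
  expect_equal(re$allele_name, sort(vlib$allele_name))
  m <- match(re$allele_name, vlib$allele_name)
  expect_equal(re$sequence, vlib$sequence[m])
  expect_equal(re$anchor, vlib$anchor[m])
  # duplicate grouping is reproduced (same partition of alleles)
  part_old <- lapply(duplicate_groups(vlib), sort)
  part_new <- lapply(duplicate_groups(re), sort)
  expect_setequal(
    vapply(part_old, paste, collapse = ",", FUN.VALUE = ""),
    vapply(part_new, paste, collapse = ",", FUN.VALUE = "")
  )
})
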