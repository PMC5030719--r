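test_that("gene-usage tabulation counts every read in the subset", {
  m <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    v_gene = "IGHV3-30", j_gene = "IGHJ3-3",
    v_allele = "IGHV3-30*01", j_allele = "IGHJ3-3*01",
    d_gene = NA, c_gene = NA,
    cdr3_nt = strrep("GCT", 4), cdr3_aa = "AAAA", cdr3_len_aa = 4L,
    length = 400L, v_divergence_pct = 2, status = "good",
    cluster_size = NA_integer_
  )
  h <- tabulate_histogram(m, "v_gene_usage")
  expect_equal(nrow(h), 1)
  expect_equal(h$value, "IGHV3-30")
  expect_equal(h$n, 10)
  expect_equal(sum(h$n), nrow(m))
  expect_error(tabulate_histogram(m, "nonsense"))
})

test_that("CDR3 net charge follows (R + K) - (D + E)", {
  expect_equal(cdr3_charge("ARDK"), 1L)
  expect_equal(cdr3_charge("ARKK"), 3L)
  expect_equal(cdr3_charge("DE"), -2L)
  expect_equal(cdr3_charge("GGSS"), 0L)
  expect_true(is.na(cdr3_charge(NA_character_)))
  m <- fix_master()
  h <- tabulate_histogram(m, "cdr3_charge", subset = "functional")
  expect_true(all(h$value == round(h$value)))
})

test_that("functional subset applies the V+J, in-frame, no-stop rules", {
  m <- fix_master()
  f <- ontorep:::subset_master(tibble::as_tibble(m), "functional")
  expect_true(all(!is.na(f$v_allele) & !is.na(f$j_allele)))
  expect_true(all(nchar(f$cdr3_nt) %% 3 == 0))
  expect_false(any(f$status %in% c("stop", "indel")))
  ids <- m$read_id[1:3]
  cust <- ontorep:::subset_master(tibble::as_tibble(m), ids)
  expect_setequal(cust$read_id, ids)
})

test_that("id-div grids conserve reads and locate single records", {
  rec <- tibble::tibble(
    read_id = "a", v_gene = "IGHV1-1",
    divergence = 4.0, mab1 = 90.0
  )
  g <- iddiv_heatmap(rec, "mab1")
  expect_equal(nrow(g), 1)
  expect_equal(g$div_bin, 4)
  expect_equal(g$id_bin, 90)
  expect_equal(g$n, 1)
  # conservation on a larger table, plus overlay warning for unknown ids
  withr::local_seed(91)
  rec2 <- tibble::tibble(
    read_id = sprintf("r%d", 1:50), v_gene = "IGHV1-1",
    divergence = runif(50, 0, 30), mab1 = runif(50, 50, 100)
  )
  expect_warning(
    g2 <- iddiv_heatmap(rec2, "mab1", overlay = c("r1", "r2", "zzz")),
    "overlay"
  )
  expect_equal(sum(g2$n), 50)
  ov <- attr(g2, "overlay")
  expect_setequal(ov$read_id, c("r1", "r2"))
  expect_error(iddiv_heatmap(rec2, "nope"), "not in records")
  p <- ggplot2::autoplot(g2)
  expect_s3_class(p, "ggplot")
})

test_that("branch colouring uses the earliest descendant birthday", {
  nwk <- "(((a:1,b:1)x:1,c:1)y:1,germ:1)root;"
  phy <- ape::read.tree(text = nwk)
  bd <- c(a = "wk34", b = "wk59", c = "wk59")
  labels <- c("wk08", "wk34", "wk59")
  cols <- ontorep:::branch_birthdays(phy, bd, labels)
  ntip <- 4
  node_x <- ntip + match("x", phy$node.label)
  node_y <- ntip + match("y", phy$node.label)
  expect_equal(cols[node_x], "wk34") # above the {wk34, wk59} pair
  expect_equal(cols[node_y], "wk34")
  expect_true(is.na(cols[match("germ", phy$tip.label)]))
})

test_that("tree rendering returns a plot and its legend table", {
  nwk <- "(((a:1,b:1)x:1,c:1)y:1,germ:1)root;"
  phy <- ape::read.tree(text = nwk)
  bd <- c(a = "wk34", b = "wk34", c = "wk34")
  labels <- c("wk08", "wk34", "wk59")
  rt <- render_tree(phy, bd, labels, label_nodes = c("a", "x"))
  expect_s3_class(rt$plot, "ggplot")
  expect_equal(rt$legend$label, labels)
  # single-time-point data: exactly one colour class among NGS branches
  cols <- ontorep:::branch_birthdays(phy, bd, labels)
  expect_equal(unique(cols[!is.na(cols)]), "wk34")
  expect_warning(render_tree(phy, bd, labels, label_nodes = "nope"), "not in tree")
})
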