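as_seed_tbl <- function(seeds) {
  if (is.character(seeds) && length(seeds) == 1 && file.exists(seeds)) {
    seeds <- read_seqs(seeds)
  }
  if (is.character(seeds)) {
    if (is.null(names(seeds))) abort("seed sequences must be named")
    seeds <- tibble(read_id = names(seeds), sequence = unname(seeds))
  }
  stopifnot(all(c("read_id", "sequence") %in% names(seeds)))
  mutate(as_tibble(seeds), sequence = normalize_dna(.data$sequence, .data$read_id))
}

#' Identity-divergence table
#'
#' For every read with a V assignment, computes (i) percent divergence from
#' the assigned germline V gene — mismatch percentage over a global
#' alignment of the read's V-matched region to the matched region of the
#' germline allele — and (ii) percent identity of the full read to each
#' seed antibody (global alignment; gap columns count as mismatches in
#' both). These are the coordinates of the identity-divergence plot.
#'
#' @param master table from [annotate_reads()].
#' @param seeds seed antibodies: FASTA path, named character vector, or
#'   tibble with `read_id`, `sequence`.
#' @param lib germline library used for annotation.
#' @param params [align_params()].
#' @return tibble with `read_id`, `v_gene`, `divergence`, and one identity
#'   column per seed (named by seed id). Reads without a V hit are skipped
#'   (message with the count).
#' @export
calc_id_div <- function(master, seeds, lib, params = align_params()) {
  seeds <- as_seed_tbl(seeds)
  x <- as_tibble(master)
  skipped <- sum(is.na(x$v_allele))
  if (skipped > 0) {
    message(sprintf("calc_id_div: skipping %d reads without a V hit", skipped))
  }
  x <- filter(x, !is.na(.data$v_allele))
  vlib <- lib_segment(lib, "V")
  vseq <- setNames(vlib$sequence, vlib$allele_name)
  div <- map_dbl(seq_len(nrow(x)), function(i) {
    region <- substr(x$sequence[i], x$v_read_start[i] + 1L, x$v_read_end[i])
    ref <- substr(
      vseq[[x$v_allele[i]]], x$v_ref_start[i] + 1L, x$v_ref_end[i]
    )
    d <- aln_detail(region, ref, params, type = "global")
    100 * (1 - d$matches / d$columns)
  })
  out <- tibble(read_id = x$read_id, v_gene = x$v_gene, divergence = div)
  for (k in seq_len(nrow(seeds))) {
    out[[seeds$read_id[k]]] <- map_dbl(x$sequence, function(s) {
      d <- aln_detail(s, seeds$sequence[k], params, type = "global")
      100 * d$matches / d$columns
    })
  }
  class(out) <- c("iddiv_records", class(out))
  out
}

#' Define an identity-divergence island
#'
#' A closed rectangle on the identity-divergence plane used to capture the
#' high-identity island formed by transcripts of the seed's lineage.
#'
#' @param seed_name seed antibody id (a column of the id-div table).
#' @param min_identity,max_identity identity bounds (percent, inclusive).
#' @param min_divergence,max_divergence divergence bounds (percent,
#'   inclusive).
#' @return list of class `island`.
#' @export
island <- function(seed_name, min_identity, max_identity = 100,
                   min_divergence = 0, max_divergence = 100) {
  stopifnot(
    min_identity <= max_identity,
    min_divergence <= max_divergence
  )
  structure(
    list(
      seed_name = seed_name,
      min_identity = min_identity, max_identity = max_identity,
      min_divergence = min_divergence, max_divergence = max_divergence
    ),
    class = "island"
  )
}

#' Extract the reads inside an identity-divergence island
#'
#' @param records table from [calc_id_div()].
#' @param isl an [island()].
#' @return character vector of read ids whose (divergence, identity) falls
#'   inside the closed rectangle.
#' @export
get_island <- function(records, isl) {
  if (!isl$seed_name %in% names(records)) {
    abort(sprintf("unknown seed '%s' in id-div records", isl$seed_name))
  }
  idy <- records[[isl$seed_name]]
  keep <- records$divergence >= isl$min_divergence &
    records$divergence <= isl$max_divergence &
    idy >= isl$min_identity & idy <= isl$max_identity
  records$read_id[keep]
}

#' Partition reads into lineages by CDR3 identity within V/J groups
#'
#' Reads are first grouped by assigned V and J gene (gene level, not
#' allele), then greedily clustered on CDR3 nucleotide identity
#' ([greedy_cluster()]); each cluster is a distinct lineage. Seed
#' antibodies, if given as annotated rows, take part in the clustering and
#' any lineage containing a seed is flagged seeded.
#'
#' @param master annotated reads carrying `v_gene`, `j_gene`, `cdr3_nt`.
#' @param identity CDR3 identity threshold (default 0.90).
#' @param seeds optional annotated seed rows (same columns as `master`).
#' @param params [align_params()].
#' @return tibble with one row per lineage: `lineage_id`, `v_gene`,
#'   `j_gene`, `size`, `representative_cdr3_nt`, `seeded`, `method`,
#'   `member_ids`, `seed_names`.
#' @export
cluster_cdr3_lineages <- function(master, identity = 0.90, seeds = NULL,
                                  params = align_params()) {
  x <- as_tibble(master)
  x$.is_seed <- FALSE
  if (!is.null(seeds)) {
    seeds <- as_tibble(seeds)
    seeds$.is_seed <- TRUE
    x <- bind_rows(x, seeds)
  }
  n_skip <- sum(is.na(x$cdr3_nt) | is.na(x$v_gene) | is.na(x$j_gene))
  if (n_skip > 0) {
    message(sprintf("cluster_cdr3_lineages: skipping %d reads without V/J/CDR3", n_skip))
  }
  x <- filter(x, !is.na(.data$cdr3_nt), !is.na(.data$v_gene), !is.na(.data$j_gene))
  groups <- split(x, paste(x$v_gene, x$j_gene, sep = "\r"))
  out <- imap(groups, function(g, key) {
    cl <- greedy_cluster(g, identity, seq = "cdr3_nt", params = params)
    seed_ids <- g$read_id[g$.is_seed]
    tibble(
      v_gene = g$v_gene[1], j_gene = g$j_gene[1],
      size = cl$size,
      representative_cdr3_nt = cl$centroid_seq,
      member_ids = cl$member_ids,
      seed_names = map(cl$member_ids, function(m) intersect(m, seed_ids)),
      seeded = map_int(seed_names, length) > 0
    )
  })
  out <- bind_rows(out) |>
    arrange(desc(.data$size), .data$v_gene, .data$j_gene) |>
    mutate(
      lineage_id = sprintf("lineage%04d", row_number()),
      method = "cdr3_cluster"
    ) |>
    select(
      "lineage_id", "v_gene", "j_gene", "size", "representative_cdr3_nt",
      "seeded", "method", "member_ids", "seed_names"
    )
  class(out) <- c("lineage_tbl", class(out))
  out
}

#' Write lineage tables and per-lineage FASTA files
#'
#' @param lineages tibble from [cluster_cdr3_lineages()].
#' @param master the annotated reads the lineages refer to.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_lineages <- function(lineages, master, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- lineages |>
    as_tibble() |>
    mutate(seed_names = map_chr(.data$seed_names, paste, collapse = ",")) |>
    select(
      "lineage_id", "v_gene", "j_gene", "size",
      "representative_cdr3_nt", "seeded", "seed_names"
    )
  readr::write_tsv(tab, file.path(dir, "lineages.tsv"))
  seqs <- setNames(master$sequence, master$read_id)
  for (i in seq_len(nrow(lineages))) {
    ids <- intersect(lineages$member_ids[[i]], names(seqs))
    if (length(ids) == 0) next
    write_fasta(
      setNames(seqs[ids], ids),
      file.path(dir, paste0(lineages$lineage_id[i], ".fasta"))
    )
  }
  invisible(dir)
}
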