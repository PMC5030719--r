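READ_STATUSES <- c(
  "good", "unique", "indel", "stop", "no_V", "no_J", "no_CDR3", "wrong_length"
)

#' Filter reads by length
#'
#' Reads too short or too long to be an antibody variable region are
#' discarded (bounds inclusive). Removed reads are returned with status
#' `wrong_length` in the `discarded` attribute.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param min_len,max_len inclusive length window (defaults 300-600 nt).
#' @return the retained reads; discarded reads are attached as
#'   `attr(, "discarded")` with a `status` column.
#' @export
filter_by_length <- function(reads, min_len = 300, max_len = 600) {
  stopifnot(min_len < max_len)
  len <- nchar(reads$sequence)
  keep <- len >= min_len & len <= max_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "discarded") <- mutate(reads[!keep, , drop = FALSE],
    status = "wrong_length"
  )
  out
}

empty_hit <- function() {
  tibble(
    allele_name = NA_character_, gene_name = NA_character_,
    score = NA_real_, read_start = NA_integer_, read_end = NA_integer_,
    ref_start = NA_integer_, ref_end = NA_integer_, strand = NA_character_,
    mismatches = NA_integer_, gaps = NA_integer_, columns = NA_integer_
  )
}

hit_from_detail <- function(d, row, strand = "+", offset = 0L) {
  tibble(
    allele_name = row$allele_name, gene_name = row$gene_name,
    score = d$score,
    read_start = d$pat_start + offset, read_end = d$pat_end + offset,
    ref_start = d$sub_start, ref_end = d$sub_end,
    strand = strand,
    mismatches = d$mismatches, gaps = d$gaps, columns = d$columns
  )
}

# score all seqs against all alleles; returns a numeric matrix seqs x alleles
score_matrix <- function(seqs, alleles, params) {
  m <- vapply(
    alleles$sequence,
    function(a) aln_scores(seqs, a, params, type = "local"),
    numeric(length(seqs))
  )
  matrix(m, nrow = length(seqs), ncol = nrow(alleles))
}

# batch segment assignment over per-read subregions [from, to); returns a
# hit tibble (one row per read, NA rows where absent) with the winning
# alignment detail (coordinates shifted to full-read space) as a list-col
batch_segment <- function(seqs, active, from, to, slib, params, min_score) {
  n <- length(seqs)
  hit_rows <- rep(list(empty_hit()), n)
  detail <- vector("list", n)
  regions <- rep("", n)
  finish <- function() {
    out <- bind_rows(hit_rows)
    out$detail <- detail
    out
  }
  idx <- which(active & !is.na(from) & !is.na(to) & to - from >= 4)
  if (length(idx) == 0) return(finish())
  regions[idx] <- substr(seqs[idx], from[idx] + 1L, to[idx])
  scores <- vapply(
    slib$sequence,
    function(a) aln_scores(regions[idx], a, params, type = "local"),
    numeric(length(idx))
  )
  scores <- matrix(scores, nrow = length(idx), ncol = nrow(slib))
  winner <- rep(NA_integer_, n)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (max(scores[k, ]) < min_score) next
    winner[i] <- pick_winner(scores[k, ], slib, regions[i], params)
  }
  for (a in unique(winner[!is.na(winner)])) {
    grp <- which(!is.na(winner) & winner == a)
    ds <- aln_detail_batch(regions[grp], slib$sequence[a], params, "local")
    for (k in seq_along(grp)) {
      i <- grp[k]
      d <- ds[[k]]
      d$pat_start <- d$pat_start + from[i]
      d$pat_end <- d$pat_end + from[i]
      hit_rows[[i]] <- hit_from_detail(d, slib[a, ], "+")
      detail[[i]] <- d
    }
  }
  finish()
}

# resolve the winning allele for one read given its candidate set: detail
# alignments break score ties by fewer gaps, then lexicographic allele name
resolve_hit <- function(seq, cand, params, strand, offset = 0L) {
  details <- map(seq_len(nrow(cand)), function(i) {
    aln_detail(seq, cand$sequence[i], params, type = "local")
  })
  gaps <- map_int(details, function(d) as.integer(d$gaps))
  ord <- order(gaps, cand$allele_name)
  i <- ord[1]
  list(
    hit = hit_from_detail(details[[i]], cand[i, ], strand, offset),
    detail = details[[i]]
  )
}

#' Assign the germline V gene of a read
#'
#' Local alignment of the read (both strands) against every V allele. A hit
#' is returned only if its score reaches `min_score_v` and the alignment
#' covers at least `min_cover_v` of the reference. Score ties are broken by
#' fewer gaps, then lexicographic allele name. The top allele is reported
#' but downstream grouping always uses the gene.
#'
#' @param read nucleotide sequence.
#' @param lib germline library containing a V segment.
#' @param params [align_params()].
#' @return one-row tibble (the hit, intervals 0-based half-open; a `-`
#'   strand means downstream steps should use the reverse complement), or
#'   NULL when no acceptable hit exists.
#' @export
assign_v <- function(read, lib, params = align_params()) {
  vlib <- lib_segment(lib, "V")
  res <- annotate_reads_v(c(read), vlib, params)
  if (is.na(res$hits$allele_name[1])) NULL else res$hits[1, ]
}

# choose the winning allele index per read from a score row; ties between
# identically-sequenced alleles go to the lexicographically first name,
# other ties are resolved by detail alignment (fewer gaps, then name)
pick_winner <- function(scores_row, slib, seq, params) {
  best <- max(scores_row)
  cand_idx <- which(scores_row == best)
  if (length(cand_idx) == 1) return(cand_idx)
  cand <- slib[cand_idx, , drop = FALSE]
  if (length(unique(cand$sequence)) == 1) {
    return(cand_idx[order(cand$allele_name)[1]])
  }
  r <- resolve_hit(seq, cand, params, "+")
  cand_idx[match(r$hit$allele_name, cand$allele_name)]
}

# batch V assignment; returns hits tibble + oriented sequences + details
annotate_reads_v <- function(seqs, vlib, params) {
  fwd <- score_matrix(seqs, vlib, params)
  rev <- score_matrix(revcomp(seqs), vlib, params)
  n <- length(seqs)
  hit_rows <- rep(list(empty_hit()), n)
  details <- vector("list", n)
  oriented <- seqs
  best_f <- apply(fwd, 1, max)
  best_r <- apply(rev, 1, max)
  accept <- pmax(best_f, best_r) >= params$min_score_v
  strand <- ifelse(best_f >= best_r, "+", "-")
  minus <- accept & strand == "-"
  if (any(minus)) oriented[minus] <- revcomp(seqs[minus])
  winner <- rep(NA_integer_, n)
  for (i in which(accept)) {
    row_scores <- if (strand[i] == "+") fwd[i, ] else rev[i, ]
    winner[i] <- pick_winner(row_scores, vlib, oriented[i], params)
  }
  for (a in unique(winner[!is.na(winner)])) {
    grp <- which(!is.na(winner) & winner == a)
    ds <- aln_detail_batch(oriented[grp], vlib$sequence[a], params, "local")
    ref_len <- nchar(vlib$sequence[a])
    for (k in seq_along(grp)) {
      i <- grp[k]
      d <- ds[[k]]
      if ((d$sub_end - d$sub_start) < params$min_cover_v * ref_len) next
      hit_rows[[i]] <- hit_from_detail(d, vlib[a, ], strand[i])
      details[[i]] <- d
    }
  }
  list(hits = bind_rows(hit_rows), details = details, oriented = oriented)
}

#' Assign the germline J gene downstream of the V hit
#'
#' Only the portion of the read after the 3' end of the V match is scanned;
#' returned coordinates are in full-read space.
#'
#' @param read nucleotide sequence (oriented as by the V hit).
#' @param v_hit one-row tibble from [assign_v()].
#' @param lib germline library containing a J segment.
#' @param params [align_params()].
#' @return one-row hit tibble or NULL.
#' @export
assign_j <- function(read, v_hit, lib, params = align_params()) {
  if (is.null(v_hit)) abort("assign_j requires a V hit")
  jlib <- lib_segment(lib, "J")
  region <- substr(read, v_hit$read_end + 1L, nchar(read))
  if (nchar(region) == 0) return(NULL)
  scores <- map_dbl(jlib$sequence, function(a) {
    aln_scores(region, a, params, type = "local")
  })
  best <- max(scores)
  if (best < params$min_score_j) return(NULL)
  cand <- jlib[scores == best, , drop = FALSE]
  r <- resolve_hit(region, cand, params, v_hit$strand, offset = v_hit$read_end)
  r$hit
}

#' Assign D and constant-region genes within the regions they can occupy
#'
#' The D gene is searched only between the V and J matches; the constant
#' region only after the J match. Either search can be disabled. D hits
#' below `min_score_d` (default equivalent to 5 consecutive matches) are
#' reported absent.
#'
#' @param read oriented read sequence.
#' @param v_hit,j_hit hits from [assign_v()] / [assign_j()].
#' @param lib germline library.
#' @param params [align_params()].
#' @param do_d,do_c enable each search.
#' @return list with elements `d` and `c` (one-row hit tibbles or NULL).
#' @export
assign_d_and_c <- function(read, v_hit, j_hit, lib, params = align_params(),
                           do_d = TRUE, do_c = TRUE) {
  search <- function(region, seg, min_score, offset) {
    if (nchar(region) < 4 || !any(lib$segment == seg)) return(NULL)
    slib <- lib_segment(lib, seg)
    scores <- map_dbl(slib$sequence, function(a) {
      aln_scores(region, a, params, type = "local")
    })
    best <- max(scores)
    if (best < min_score) return(NULL)
    cand <- slib[scores == best, , drop = FALSE]
    resolve_hit(region, cand, params, v_hit$strand, offset = offset)$hit
  }
  d <- if (do_d) {
    search(
      substr(read, v_hit$read_end + 1L, j_hit$read_start),
      "D", params$min_score_d, v_hit$read_end
    )
  }
  c_hit <- if (do_c) {
    search(
      substr(read, j_hit$read_end + 1L, nchar(read)),
      "C", params$min_score_c, j_hit$read_end
    )
  }
  list(d = d, c = c_hit)
}

# map a reference anchor position into read coordinates through an
# alignment detail; anchors within `flank` nt beyond the aligned interval
# are mapped by ungapped extrapolation from the nearest aligned column
map_anchor <- function(d, anchor, flank = 15L) {
  if (is.na(anchor)) return(NA_integer_)
  if (anchor >= d$sub_start && anchor < d$sub_end) {
    m <- ref_to_read_map(d)
    return(m[anchor - d$sub_start + 1L])
  }
  if (anchor < d$sub_start && d$sub_start - anchor <= flank) {
    return(d$pat_start - (d$sub_start - anchor))
  }
  if (anchor >= d$sub_end && anchor - d$sub_end < flank) {
    return(d$pat_end + (anchor - d$sub_end))
  }
  NA_integer_
}

#' Extract the CDR3 junction of a read
#'
#' Maps the V allele's conserved-Cys (IMGT 104) anchor and the J allele's
#' W/F (IMGT 118) anchor through the respective alignments into read
#' coordinates; the CDR3 is the stretch strictly between the two anchor
#' codons (IMGT 105-117). Absent when an anchor cannot be mapped or the
#' interval is empty.
#'
#' @param read oriented read sequence.
#' @param v_hit,j_hit segment hits.
#' @param lib germline library with anchors ([annotate_anchors()]).
#' @param params [align_params()].
#' @return list with `cdr3_nt` and `cdr3_aa` (NA when absent or out of
#'   frame).
#' @export
extract_cdr3 <- function(read, v_hit, j_hit, lib, params = align_params()) {
  v_row <- lib[lib$allele_name == v_hit$allele_name & lib$segment == "V", ]
  j_row <- lib[lib$allele_name == j_hit$allele_name & lib$segment == "J", ]
  if (nrow(v_row) == 0 || nrow(j_row) == 0) abort("hit allele not in library")
  if (isTRUE(v_row$unanchored) || isTRUE(j_row$unanchored)) {
    return(list(cdr3_nt = NA_character_, cdr3_aa = NA_character_))
  }
  v_d <- aln_detail(
    substr(read, v_hit$read_start + 1L, v_hit$read_end),
    v_row$sequence, params, "local"
  )
  v_d$pat_start <- v_d$pat_start + v_hit$read_start
  v_d$pat_end <- v_d$pat_end + v_hit$read_start
  j_d <- aln_detail(
    substr(read, j_hit$read_start + 1L, j_hit$read_end),
    j_row$sequence, params, "local"
  )
  j_d$pat_start <- j_d$pat_start + j_hit$read_start
  j_d$pat_end <- j_d$pat_end + j_hit$read_start
  cdr3_from_details(read, v_d, j_d, v_row$anchor, j_row$anchor)
}

cdr3_from_details <- function(read, v_d, j_d, v_anchor, j_anchor) {
  absent <- list(cdr3_nt = NA_character_, cdr3_aa = NA_character_)
  if (is.na(v_anchor) || is.na(j_anchor)) return(absent)
  v_pos <- map_anchor(v_d, v_anchor)
  j_pos <- map_anchor(j_d, j_anchor)
  if (is.na(v_pos) || is.na(j_pos)) return(absent)
  start <- v_pos + 3L
  if (start >= j_pos || start < 0 || j_pos > nchar(read)) return(absent)
  nt <- substr(read, start + 1L, j_pos)
  aa <- if (nchar(nt) %% 3 == 0) translate_nt(nt) else NA_character_
  list(cdr3_nt = nt, cdr3_aa = aa)
}

# in-frame stop-codon scan across the V-J span; frame propagated from the
# germline V reading frame (frame 0 of the reference) through the alignment
has_stop_in_frame <- function(read, v_hit, j_hit) {
  start <- v_hit$read_start + ((3L - (v_hit$ref_start %% 3L)) %% 3L)
  end <- j_hit$read_end
  p <- start
  while (p + 3L <= end) {
    if (substr(read, p + 1L, p + 3L) %in% STOP_CODONS) return(TRUE)
    p <- p + 3L
  }
  FALSE
}

#' Final status of an annotated read
#'
#' Applies the status precedence wrong_length > no_V > no_J > no_CDR3 >
#' indel > stop > good. A read is `indel` when the total gap length within
#' its V or its J alignment is not divisible by 3 (strict mode flags any
#' gapped V alignment); `stop` when an in-frame stop codon occurs in the
#' reading frame propagated from the germline V across the V-J span.
#'
#' @param row one row of the master table (as built by [annotate_reads()]).
#' @param strict_indel flag any V-alignment gap opening as indel.
#' @return status string.
#' @export
classify_status <- function(row, strict_indel = FALSE) {
  if (!is.na(row$status) && row$status == "wrong_length") return("wrong_length")
  if (is.na(row$v_allele)) return("no_V")
  if (is.na(row$j_allele)) return("no_J")
  if (is.na(row$cdr3_nt)) return("no_CDR3")
  if (row$v_gaps %% 3 != 0 || row$j_gaps %% 3 != 0) return("indel")
  if (strict_indel && row$v_gaps > 0) return("indel")
  if (isTRUE(row$has_stop)) return("stop")
  "good"
}

prefix_hit <- function(hit, prefix) {
  if (is.null(hit)) hit <- empty_hit()
  names(hit) <- paste0(prefix, "_", names(hit))
  names(hit)[names(hit) == paste0(prefix, "_allele_name")] <- paste0(prefix, "_allele")
  names(hit)[names(hit) == paste0(prefix, "_gene_name")] <- paste0(prefix, "_gene")
  hit
}

#' Annotate a set of reads against a germline library
#'
#' The full annotation pass: length filtering, V assignment (both strands;
#' minus-strand reads are reverse complemented), J assignment downstream of
#' the V, optional D and constant-region assignment, CDR3 extraction via
#' the anchor positions, germline divergence, and final status assignment.
#'
#' @param reads tibble with `read_id` and `sequence` (e.g. from
#'   [read_seqs()]), or a path to a FASTA/FASTQ file.
#' @param lib germline library (all segments bound together) with anchors.
#' @param params [align_params()].
#' @param min_len,max_len length window (see [filter_by_length()]).
#' @param do_d,do_c enable D / constant-region assignment.
#' @param strict_indel see [classify_status()].
#' @return master table: one row per input read with assignment columns
#'   (`v_allele`, `v_gene`, coordinates, `j_*`, `d_*`, `c_*`), `cdr3_nt`,
#'   `cdr3_aa`, `cdr3_len_aa`, `v_divergence_pct`, and `status`. Reads on
#'   the minus strand have `sequence` replaced by its reverse complement.
#' @export
annotate_reads <- function(reads, lib, params = align_params(),
                           min_len = 300, max_len = 600,
                           do_d = TRUE, do_c = TRUE,
                           strict_indel = FALSE) {
  if (is.character(reads) && length(reads) == 1) reads <- read_seqs(reads)
  if (anyDuplicated(reads$read_id)) abort("duplicate read_id in input")
  lib <- annotate_anchors(lib)
  kept <- filter_by_length(reads, min_len, max_len)
  disc <- attr(kept, "discarded")
  vlib <- lib_segment(lib, "V")
  v_anchor <- setNames(vlib$anchor, vlib$allele_name)
  jlib <- lib_segment(lib, "J")
  j_anchor <- setNames(jlib$anchor, jlib$allele_name)

  n <- nrow(kept)
  rows <- vector("list", n)
  if (n > 0) {
    vres <- annotate_reads_v(kept$sequence, vlib, params)
    oriented <- vres$oriented
    has_v <- !is.na(vres$hits$allele_name)
    # batch J scoring on the region downstream of each V match
    j_best <- batch_segment(
      oriented, has_v,
      from = ifelse(has_v, vres$hits$read_end, NA_integer_),
      to = nchar(oriented),
      slib = jlib, params = params, min_score = params$min_score_j
    )
    has_j <- !is.na(j_best$allele_name)
    d_best <- if (do_d && any(lib$segment == "D")) {
      batch_segment(
        oriented, has_v & has_j,
        from = ifelse(has_v, vres$hits$read_end, NA_integer_),
        to = ifelse(has_j, j_best$read_start, NA_integer_),
        slib = lib_segment(lib, "D"), params = params,
        min_score = params$min_score_d
      )
    }
    c_best <- if (do_c && any(lib$segment == "C")) {
      batch_segment(
        oriented, has_v & has_j,
        from = ifelse(has_j, j_best$read_end, NA_integer_),
        to = nchar(oriented),
        slib = lib_segment(lib, "C"), params = params,
        min_score = params$min_score_c
      )
    }
    for (i in seq_len(n)) {
      seq <- oriented[i]
      v_hit <- if (has_v[i]) vres$hits[i, ] else NULL
      j_hit <- if (has_j[i]) j_best[i, c(
        "allele_name", "gene_name", "score", "read_start", "read_end",
        "ref_start", "ref_end", "strand", "mismatches", "gaps", "columns"
      )] else NULL
      if (!is.null(j_hit)) j_hit$strand <- v_hit$strand
      cdr3 <- list(cdr3_nt = NA_character_, cdr3_aa = NA_character_)
      if (!is.null(v_hit) && !is.null(j_hit)) {
        cdr3 <- cdr3_from_details(
          seq, vres$details[[i]], j_best$detail[[i]],
          unname(v_anchor[v_hit$allele_name]),
          unname(j_anchor[j_hit$allele_name])
        )
      }
      d_hit <- if (!is.null(d_best) && !is.na(d_best$allele_name[i])) {
        d_best[i, c("allele_name", "gene_name", "score")]
      }
      c_hit <- if (!is.null(c_best) && !is.na(c_best$allele_name[i])) {
        c_best[i, c("allele_name", "gene_name", "score")]
      }
      rows[[i]] <- c(
        list(read_id = kept$read_id[i], sequence = seq,
             length = nchar(seq), status = NA_character_),
        as.list(prefix_hit(v_hit, "v")), as.list(prefix_hit(j_hit, "j")),
        as.list(prefix_hit(d_hit, "d")[c("d_allele", "d_gene", "d_score")]),
        as.list(prefix_hit(c_hit, "c")[c("c_allele", "c_gene", "c_score")]),
        list(
          cdr3_nt = cdr3$cdr3_nt, cdr3_aa = cdr3$cdr3_aa,
          has_stop = if (!is.null(v_hit) && !is.null(j_hit)) {
            has_stop_in_frame(seq, v_hit, j_hit)
          } else {
            NA
          },
          v_divergence_pct = if (!is.null(v_hit)) {
            100 * (v_hit$mismatches + v_hit$gaps) / v_hit$columns
          } else {
            NA_real_
          }
        )
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(disc) > 0) {
    out <- bind_rows(out, mutate(disc, length = nchar(.data$sequence)))
  }
  out <- out |>
    mutate(
      cdr3_len_aa = ifelse(is.na(.data$cdr3_aa), NA_integer_,
        nchar(.data$cdr3_aa)
      ),
      cluster_size = NA_integer_
    )
  out$status <- vapply(
    seq_len(nrow(out)),
    function(i) classify_status(out[i, ], strict_indel),
    character(1)
  )
  out <- out[match(reads$read_id, out$read_id), , drop = FALSE]
  class(out) <- c("bcr_master", class(out))
  out
}

#' Write annotation outputs
#'
#' Emits the tab-separated master table, per-segment gene-usage summary
#' tables, and FASTA subsets mirroring the pipeline's sequence files:
#' `allOK` (V and J assigned), `goodVJ` (plus CDR3), `goodCDR3` (plus no
#' indel or stop).
#'
#' @param master table from [annotate_reads()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(master, dir) {
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sequences"), recursive = TRUE, showWarnings = FALSE)
  cols <- c(
    "read_id", "length", "v_gene", "v_allele", "j_gene", "j_allele",
    "d_gene", "c_gene", "cdr3_nt", "cdr3_aa", "cdr3_len_aa",
    "v_divergence_pct", "status", "cluster_size"
  )
  readr::write_tsv(
    select(as_tibble(master), all_of(cols)),
    file.path(dir, "tables", "master.tsv")
  )
  for (seg in c("v", "j", "d", "c")) {
    col <- paste0(seg, "_gene")
    if (!col %in% names(master)) next
    usage <- count(
      filter(as_tibble(master), !is.na(.data[[col]])),
      .data[[col]],
      name = "n"
    )
    readr::write_tsv(usage, file.path(dir, "tables", paste0(seg, "_usage.tsv")))
  }
  subsets <- list(
    allOK = !is.na(master$v_allele) & !is.na(master$j_allele),
    goodVJ = !is.na(master$cdr3_nt),
    goodCDR3 = master$status %in% c("good", "unique")
  )
  for (nm in names(subsets)) {
    sub <- master[subsets[[nm]], , drop = FALSE]
    if (nrow(sub) > 0) {
      write_fasta(sub, file.path(dir, "sequences", paste0(nm, ".fasta")))
    }
  }
  invisible(dir)
}
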