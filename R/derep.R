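#' Greedy centroid clustering of sequences
#'
#' UCLUST-style greedy clustering with a deterministic input order: exact
#' duplicates are collapsed first (their multiplicities summed), remaining
#' sequences are sorted by decreasing weight, then decreasing length, then
#' increasing id, and each sequence joins the first existing centroid (in
#' founding order) whose global-alignment identity reaches the threshold,
#' or founds a new centroid. Identity counts gap columns as mismatches.
#'
#' @param x tibble with id and sequence columns.
#' @param identity identity threshold in (0, 1].
#' @param id,seq column names.
#' @param weights optional per-row multiplicities (default 1).
#' @param params [align_params()].
#' @return tibble with one row per cluster: `cluster_id`, `centroid_id`,
#'   `centroid_seq`, `size`, `member_ids` (list column, duplicate-expanded).
#' @export
greedy_cluster <- function(x, identity, id = "read_id", seq = "sequence",
                           weights = NULL, params = align_params()) {
  stopifnot(identity > 0, identity <= 1)
  ids <- x[[id]]
  seqs <- x[[seq]]
  w <- weights %||% rep(1L, length(ids))
  # collapse exact duplicates
  grp <- split(seq_along(seqs), seqs)
  uniq <- tibble(
    sequence = names(grp),
    size = map_int(grp, function(ii) sum(w[ii])),
    rep_id = map_chr(grp, function(ii) sort(ids[ii])[1]),
    members = map(grp, function(ii) ids[ii])
  )
  uniq <- uniq[order(-uniq$size, -nchar(uniq$sequence), uniq$rep_id), ]
  cent_seq <- character(0)
  cent_rows <- list()
  assign_to <- integer(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    placed <- 0L
    for (ci in seq_along(cent_seq)) {
      d <- aln_detail(uniq$sequence[i], cent_seq[ci], params, type = "global")
      if (d$matches / d$columns >= identity) {
        placed <- ci
        break
      }
    }
    if (placed == 0L) {
      cent_seq <- c(cent_seq, uniq$sequence[i])
      placed <- length(cent_seq)
    }
    assign_to[i] <- placed
  }
  out <- map(seq_along(cent_seq), function(ci) {
    rows <- uniq[assign_to == ci, ]
    tibble(
      cluster_id = ci,
      centroid_id = rows$rep_id[1],
      centroid_seq = cent_seq[ci],
      size = sum(rows$size),
      member_ids = list(unlist(rows$members, use.names = FALSE))
    )
  })
  bind_rows(out)
}

#' Dereplicate good reads by greedy identity clustering
#'
#' Eliminates redundant transcripts and suppresses PCR/sequencing artifacts:
#' reads are greedily clustered at the identity threshold (default 99%) and
#' clusters with fewer than `min_size` members (default 3) are discarded.
#' Retained centroids are reported as the unique transcripts with status
#' `unique`.
#'
#' @param reads master table from [annotate_reads()] (rows with status
#'   `good` are clustered) or any tibble with `read_id` and `sequence`.
#' @param identity identity threshold (fraction, default 0.99).
#' @param min_size minimum cluster size to retain (default 3).
#' @param params [align_params()].
#' @return list with `clusters` (tibble: `cluster_id`, `centroid_id`,
#'   `size`, `retained`, `member_ids`) and `unique_reads` (tibble of
#'   retained centroids with `cluster_size` and status `unique`).
#' @export
dereplicate <- function(reads, identity = 0.99, min_size = 3,
                        params = align_params()) {
  stopifnot(min_size >= 1)
  x <- as_tibble(reads)
  if ("status" %in% names(x)) x <- filter(x, .data$status == "good")
  if (nrow(x) == 0) {
    return(list(
      clusters = tibble(
        cluster_id = integer(), centroid_id = character(),
        size = integer(), retained = logical(), member_ids = list()
      ),
      unique_reads = tibble(
        read_id = character(), sequence = character(),
        cluster_size = integer(), status = character()
      )
    ))
  }
  cl <- greedy_cluster(x, identity, params = params)
  cl$retained <- cl$size >= min_size
  uniq <- cl |>
    filter(.data$retained) |>
    mutate(
      read_id = .data$centroid_id,
      sequence = .data$centroid_seq,
      cluster_size = .data$size,
      status = "unique"
    ) |>
    select("read_id", "sequence", "cluster_size", "status")
  extra <- setdiff(names(x), c(names(uniq), "sequence"))
  uniq <- left_join(uniq, select(x, "read_id", all_of(extra)), by = "read_id")
  list(
    clusters = select(
      cl, "cluster_id", "centroid_id", "size", "retained", "member_ids"
    ),
    unique_reads = uniq
  )
}
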