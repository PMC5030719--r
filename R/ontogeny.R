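#' Merge lineage members across time points with birthday assignment
#'
#' Reads one FASTA per time point, collapses sequences that are identical
#' after uppercasing and degapping, and assigns each collapsed transcript a
#' "birthday": the first time point (in the supplied label order) at which
#' it was observed. Output ids are `<birthday>-<original id>`.
#'
#' @param files character vector of FASTA paths, one per time point.
#' @param labels time-point labels in temporal order (same length as
#'   `files`). The supplied order defines time; labels are never parsed.
#' @return tibble with `seq_id`, `sequence`, `birthday`, `observed_at`
#'   (list of labels), `copies` (total input records collapsed in).
#' @export
merge_timepoints <- function(files, labels) {
  stopifnot(length(files) == length(labels), length(files) >= 1)
  if (anyDuplicated(labels)) abort("time-point labels must be unique")
  recs <- map2(files, labels, function(f, lab) {
    x <- read_seqs(f)
    if (anyDuplicated(x$read_id)) {
      abort(sprintf("duplicate sequence id in %s", f))
    }
    mutate(x, label = lab)
  })
  recs <- bind_rows(recs) |>
    mutate(sequence = normalize_dna(.data$sequence, .data$read_id))
  idx <- setNames(seq_along(labels), labels)
  out <- recs |>
    group_by(.data$sequence) |>
    summarise(
      first_i = min(idx[.data$label]),
      orig_id = .data$read_id[which.min(idx[.data$label])],
      observed_at = list(labels[sort(unique(idx[.data$label]))]),
      copies = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      birthday = labels[.data$first_i],
      seq_id = paste0(.data$birthday, "-", .data$orig_id)
    ) |>
    arrange(.data$first_i, .data$seq_id) |>
    select("seq_id", "sequence", "birthday", "observed_at", "copies")
  attr(out, "labels") <- labels
  class(out) <- c("timed_seqs", class(out))
  out
}

# path of node numbers from the UCA (child of root opposite the germline
# leaf) down to a target leaf
uca_node <- function(phy, germline_id) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- phy$edge[phy$edge[, 1] == root, 2]
  germ <- match(germline_id, phy$tip.label)
  uca <- setdiff(kids, germ)
  if (length(uca) != 1) abort("root is not a germline/rest bifurcation")
  uca
}

# amino-acid distance between two node sequences; codons containing an
# in-frame stop in either sequence are excluded from the comparison
aa_changes <- function(nt1, nt2) {
  a1 <- strsplit(translate_nt(nt1), "")[[1]]
  a2 <- strsplit(translate_nt(nt2), "")[[1]]
  L <- min(length(a1), length(a2))
  a1 <- a1[seq_len(L)]
  a2 <- a2[seq_len(L)]
  ok <- a1 != "*" & a2 != "*"
  sum(a1[ok] != a2[ok])
}

#' Select developmental intermediates along the UCA-to-target path
#'
#' Walks the tree path from the unmutated common ancestor (the child of the
#' root opposite the germline outgroup) to a target leaf, accumulating
#' amino-acid changes between consecutive node sequences. With `n`, the
#' `n` path nodes closest to evenly spaced fractions of the total change
#' are chosen (ties to the earlier node); with `spacing_aa`, the next node
#' is emitted whenever at least that many changes have accumulated since
#' the last emitted node. The UCA itself is always the first row. Nodes
#' whose sequence contains an in-frame stop are compared with the stop
#' codons excluded (with a warning).
#'
#' @param x an `ontogeny_tree` from [build_ml_tree()].
#' @param target leaf id of the antibody of interest.
#' @param n number of intermediates (exclusive with `spacing_aa`).
#' @param spacing_aa approximate amino-acid changes between consecutive
#'   intermediates (exclusive with `n`).
#' @return tibble: `node`, `cum_aa`, `sequence`, `aa` — ordered from the
#'   UCA to the last selected intermediate.
#' @export
pick_intermediates <- function(x, target, n = NULL, spacing_aa = NULL) {
  stopifnot(inherits(x, "ontogeny_tree"))
  if (is.null(n) == is.null(spacing_aa)) {
    abort("give exactly one of n / spacing_aa")
  }
  phy <- x$tree
  ntip <- length(phy$tip.label)
  tgt <- match(target, phy$tip.label)
  if (is.na(tgt)) abort(sprintf("target '%s' is not a leaf", target))
  path <- ape::nodepath(phy, uca_node(phy, x$germline_id), tgt)
  seq_of <- function(node) {
    nm <- node_name(phy, node)
    if (node <= ntip) x$aln[[nm]] else x$anc[[nm]]
  }
  seqs <- vapply(path, seq_of, character(1))
  if (any(grepl("\\*", translate_nt(seqs)))) {
    warn("stop codon in a path sequence; affected codons excluded from spacing")
  }
  steps <- c(0, map_dbl(seq_along(path)[-1], function(i) {
    aa_changes(seqs[i - 1], seqs[i])
  }))
  cum <- cumsum(steps)
  labels <- vapply(path, function(nd) node_name(phy, nd), character(1))
  total <- cum[length(cum)]
  sel <- if (!is.null(n)) {
    if (total == 0) {
      integer(0)
    } else {
      targets <- seq_len(n) * total / (n + 1)
      vapply(targets, function(tg) which.min(abs(cum - tg)), integer(1))
    }
  } else {
    out <- integer(0)
    last <- 0
    for (i in seq_along(cum)[-1]) {
      if (cum[i] - last >= spacing_aa) {
        out <- c(out, i)
        last <- cum[i]
      }
    }
    out
  }
  sel <- unique(c(1L, sel))
  tibble(
    node = labels[sel],
    cum_aa = cum[sel],
    sequence = unname(seqs[sel]),
    aa = translate_nt(seqs[sel])
  )
}

#' Most recent common ancestor sequence of a set of leaves
#'
#' @param x an `ontogeny_tree`.
#' @param leaf_ids two or more leaf ids.
#' @return one-row tibble with `node` and `sequence`.
#' @export
lineage_mrca <- function(x, leaf_ids) {
  phy <- x$tree
  idx <- match(leaf_ids, phy$tip.label)
  if (anyNA(idx)) abort("unknown leaf id")
  if (length(idx) < 2) abort("need at least two leaves")
  node <- ape::getMRCA(phy, idx)
  nm <- node_name(phy, node)
  tibble(node = nm, sequence = unname(x$anc[[nm]]))
}

#' Collapse minor branches of an ontogeny tree by CDR3 similarity
#'
#' Phylogenetically aware display collapsing: in post-order, a clade is
#' collapsible when all of its NGS leaves' CDR3s are within the identity
#' threshold of the clade's plurality CDR3 and it contains no `keep` leaf.
#' Maximal collapsible clades with at least `min_size` leaves become a
#' single "major branch" pseudo-leaf labelled `<representative>|size=<n>`;
#' smaller ones are pruned. Leaves listed in `keep` (known antibodies, the
#' germline) are always displayed.
#'
#' @param tree rooted `phylo` or `ontogeny_tree`.
#' @param cdr3_map named character vector: leaf id -> CDR3 nucleotide
#'   sequence (every NGS leaf must be present).
#' @param identity CDR3 identity threshold for collapsing.
#' @param min_size minimum leaves for a major branch.
#' @param keep leaf ids always retained.
#' @param birthdays optional named vector leaf -> birthday label (used for
#'   the temporal span column of the summary).
#' @param label_order optional label order for the birthday span.
#' @param params [align_params()].
#' @return list with `tree` (collapsed `phylo`) and `summary` (tibble:
#'   `branch_id`, `size`, `birthday_span`, `representative_cdr3`) plus
#'   attributes `n_pruned`.
#' @export
collapse_minor_branches <- function(tree, cdr3_map, identity = 0.85,
                                    min_size = 5, keep = character(0),
                                    birthdays = NULL, label_order = NULL,
                                    params = align_params()) {
  phy <- if (inherits(tree, "ontogeny_tree")) tree$tree else tree
  ntip <- length(phy$tip.label)
  ngs <- setdiff(phy$tip.label, keep)
  missing_cdr3 <- setdiff(ngs, names(cdr3_map))
  if (length(missing_cdr3) > 0) {
    abort(sprintf("no CDR3 for leaves: %s", paste(head(missing_cdr3, 3), collapse = ", ")))
  }
  plurality <- function(v) {
    tt <- sort(table(v), decreasing = TRUE)
    cand <- names(tt)[tt == tt[1]]
    sort(cand)[1]
  }
  within_identity <- function(cdr3s, center) {
    all(vapply(cdr3s, function(s) {
      if (s == center) return(TRUE)
      d <- aln_detail(s, center, params, type = "global")
      d$matches / d$columns >= identity
    }, logical(1)))
  }
  nnode <- ntip + phy$Nnode
  tips_below <- vector("list", nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- phy$tip.label[i]
  post <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  collapsible <- logical(nnode)
  for (v in seq_len(nnode)) {
    tl <- tips_below[[v]]
    if (any(tl %in% keep)) next
    cdr3s <- cdr3_map[tl]
    collapsible[v] <- within_identity(cdr3s, plurality(cdr3s))
  }
  # maximal collapsible clades: collapsible node whose parent is not
  parent_of <- integer(nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  maximal <- which(vapply(seq_len(nnode), function(v) {
    collapsible[v] && (v == root || !collapsible[parent_of[v]])
  }, logical(1)))
  drop <- character(0)
  renames <- list()
  summary <- list()
  n_pruned <- 0L
  bid <- 0L
  for (v in maximal) {
    tl <- tips_below[[v]]
    if (length(tl) >= min_size) {
      bid <- bid + 1L
      cdr3s <- cdr3_map[tl]
      rep_cdr3 <- plurality(cdr3s)
      rep_leaf <- sort(tl[cdr3s == rep_cdr3])[1]
      span <- NA_character_
      if (!is.null(birthdays)) {
        bl <- birthdays[intersect(tl, names(birthdays))]
        if (length(bl) > 0) {
          ord <- label_order %||% sort(unique(bl))
          bl <- factor(bl, levels = ord)
          span <- paste(levels(bl)[range(as.integer(bl))], collapse = "-")
        }
      }
      new_label <- sprintf("%s|size=%d", rep_leaf, length(tl))
      renames[[rep_leaf]] <- new_label
      drop <- c(drop, setdiff(tl, rep_leaf))
      summary[[bid]] <- tibble(
        branch_id = new_label, size = length(tl),
        birthday_span = span, representative_cdr3 = rep_cdr3
      )
    } else {
      drop <- c(drop, tl)
      n_pruned <- n_pruned + length(tl)
    }
  }
  out <- if (length(drop) > 0) ape::drop.tip(phy, drop) else phy
  if (length(renames) > 0) {
    m <- match(names(renames), out$tip.label)
    out$tip.label[m] <- unlist(renames)
  }
  structure(
    list(tree = out, summary = bind_rows(summary)),
    n_pruned = n_pruned
  )
}

#' Partition an alignment into region and codon-position column sets
#'
#' Builds the five partitions used for evolutionary-rate analysis: the full
#' V(D)J alignment, the CDR union, the framework (FWR) union, codon
#' positions 1+2, and codon position 3.
#'
#' @param n_col alignment length in columns (must be divisible by 3).
#' @param region_map character vector of length `n_col` assigning every
#'   column to one of FWR1-3 / CDR1-3 (the label `junction` is accepted as
#'   an alias for CDR3).
#' @return named list of integer column-index vectors (1-based):
#'   `vdj`, `cdr`, `fwr`, `pos12`, `pos3`.
#' @export
partition_alignment <- function(n_col, region_map) {
  if (n_col %% 3 != 0) abort("alignment length must be divisible by 3")
  if (length(region_map) != n_col) {
    abort("region_map must label every alignment column")
  }
  region_map[region_map == "junction"] <- "CDR3"
  valid <- c(paste0("FWR", 1:3), paste0("CDR", 1:3))
  bad <- which(!region_map %in% valid)
  if (length(bad) > 0) {
    abort(sprintf(
      "region_map has unknown/missing labels at columns: %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  cols <- seq_len(n_col)
  list(
    vdj = cols,
    cdr = cols[startsWith(region_map, "CDR")],
    fwr = cols[startsWith(region_map, "FWR")],
    pos12 = cols[(cols - 1L) %% 3L < 2L],
    pos3 = cols[(cols - 1L) %% 3L == 2L]
  )
}

# compress sorted integer columns into NEXUS charset tokens (a-b, or a-b\3
# for constant-stride runs of step 3)
charset_tokens <- function(cols) {
  if (length(cols) == 0) return(character(0))
  if (length(cols) >= 3 && all(diff(cols) == 3)) {
    return(sprintf("%d-%d\\3", cols[1], cols[length(cols)]))
  }
  runs <- split(cols, cumsum(c(1, diff(cols) != 1)))
  vapply(runs, function(r) {
    if (length(r) == 1) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, character(1))
}

#' Write partitions as a NEXUS sets block
#'
#' @param partitions list from [partition_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus_sets <- function(partitions, path) {
  lines <- c("#NEXUS", "begin sets;")
  for (nm in names(partitions)) {
    toks <- charset_tokens(partitions[[nm]])
    lines <- c(lines, sprintf("  charset %s = %s;", nm, paste(toks, collapse = " ")))
  }
  lines <- c(lines, "end;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS sets block back into column-index sets
#'
#' @param path NEXUS file written by [write_nexus_sets()].
#' @return named list of integer vectors.
#' @export
read_nexus_sets <- function(path) {
  lines <- readLines(path)
  cs <- grep("^\\s*charset ", lines, value = TRUE)
  out <- list()
  for (ln in cs) {
    nm <- sub("^\\s*charset\\s+(\\S+)\\s*=.*$", "\\1", ln)
    body <- sub("^.*=\\s*", "", sub(";\\s*$", "", ln))
    toks <- strsplit(trimws(body), "\\s+")[[1]]
    cols <- integer(0)
    for (tk in toks) {
      if (grepl("\\\\3$", tk)) {
        r <- as.integer(strsplit(sub("\\\\3$", "", tk), "-")[[1]])
        cols <- c(cols, seq(r[1], r[2], by = 3L))
      } else if (grepl("-", tk)) {
        r <- as.integer(strsplit(tk, "-")[[1]])
        cols <- c(cols, seq(r[1], r[2]))
      } else {
        cols <- c(cols, as.integer(tk))
      }
    }
    out[[nm]] <- cols
  }
  out
}

#' Write an ontogeny tree and its ancestral sequences
#'
#' Newick with internal node labels plus a FASTA of inferred ancestors.
#'
#' @param x an `ontogeny_tree`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ontogeny <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(x$tree, file.path(dir, "lineage.nwk"))
  write_fasta(x$anc, file.path(dir, "ancestors.fasta"))
  invisible(dir)
}
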