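#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

HIST_VARIABLES <- c(
  "v_gene_usage", "j_gene_usage", "d_gene_usage", "c_usage",
  "cdr3_len_aa", "v_divergence_pct", "read_length", "status", "cdr3_charge"
)

#' CDR3 net charge
#'
#' (#R + #K) - (#D + #E) per CDR3 amino-acid sequence.
#'
#' @param aa character vector of CDR3 amino-acid sequences.
#' @return integer vector (NA for NA input).
#' @export
cdr3_charge <- function(aa) {
  pos <- stringr::str_count(aa, "[RK]")
  neg <- stringr::str_count(aa, "[DE]")
  as.integer(pos - neg)
}

subset_master <- function(x, subset) {
  if (is.character(subset) && length(subset) == 1) {
    switch(subset,
      all = x,
      functional = filter(
        x,
        !is.na(.data$v_allele), !is.na(.data$j_allele),
        !is.na(.data$cdr3_nt), nchar(.data$cdr3_nt) %% 3 == 0,
        !.data$status %in% c("stop", "indel")
      ),
      unique = filter(x, .data$status == "unique" |
        (!is.na(.data$cluster_size) & .data$cluster_size > 0)),
      abort(sprintf("unknown subset '%s'", subset))
    )
  } else {
    filter(x, .data$read_id %in% subset)
  }
}

#' Tabulate a repertoire histogram
#'
#' Counts per bin or category for one repertoire property, optionally per
#' sample/time point. The `functional` subset keeps reads with successful V
#' and J assignment, an in-frame junction, and no stop codon; `unique`
#' keeps dereplicated transcripts; a character vector of read ids selects a
#' custom subset.
#'
#' @param master annotated reads (one or more master tables bound together).
#' @param variable one of `r paste(HIST_VARIABLES, collapse = ", ")`.
#' @param subset `"all"`, `"functional"`, `"unique"`, or a vector of ids.
#' @param bins numeric bin edges for numeric variables (default: integer
#'   bins for lengths/charge, width-1 bins for divergence).
#' @param by optional grouping column (e.g. `"timepoint"`).
#' @return tibble of counts with class `repertoire_hist`.
#' @export
tabulate_histogram <- function(master, variable, subset = "all", bins = NULL,
                               by = NULL) {
  variable <- match.arg(variable, HIST_VARIABLES)
  x <- subset_master(as_tibble(master), subset)
  val <- switch(variable,
    v_gene_usage = x$v_gene,
    j_gene_usage = x$j_gene,
    d_gene_usage = x$d_gene,
    c_usage = x$c_gene,
    cdr3_len_aa = x$cdr3_len_aa,
    v_divergence_pct = x$v_divergence_pct,
    read_length = x$length,
    status = x$status,
    cdr3_charge = cdr3_charge(x$cdr3_aa)
  )
  g <- if (!is.null(by)) x[[by]] else factor(rep("all", nrow(x)))
  keep <- !is.na(val)
  val <- val[keep]
  g <- g[keep]
  if (is.numeric(val) && !is.null(bins)) {
    if (is.unsorted(bins, strictly = TRUE)) abort("bins must be strictly increasing")
    val <- cut(val, breaks = bins, include.lowest = TRUE)
  }
  out <- tibble(group = as.character(g), value = val) |>
    count(.data$group, .data$value, name = "n") |>
    arrange(.data$group, .data$value)
  attr(out, "variable") <- variable
  class(out) <- c("repertoire_hist", class(out))
  out
}

#' Bin an identity-divergence table into a heat-map grid
#'
#' Counts reads in `bin_width`-sized cells over the \[0, 100\] x \[0, 100\]
#' divergence-identity plane for one seed. Optional overlay ids are
#' returned as explicit points (ids absent from the table produce a
#' warning and are skipped). When `by` names a column (e.g. a time-point
#' label added to the records), one grid per group is produced with shared
#' axes.
#'
#' @param records table from [calc_id_div()].
#' @param seed_name seed column to use for the identity axis.
#' @param bin_width bin width in percentage points (default 1).
#' @param overlay optional read ids to mark.
#' @param by optional grouping column in `records`.
#' @return tibble (`group`, `div_bin`, `id_bin`, `n`) of class
#'   `iddiv_grid`; overlay points in `attr(, "overlay")`.
#' @export
iddiv_heatmap <- function(records, seed_name, bin_width = 1, overlay = NULL,
                          by = NULL) {
  if (!seed_name %in% names(records)) {
    abort(sprintf("seed '%s' not in records", seed_name))
  }
  g <- if (!is.null(by)) records[[by]] else rep("all", nrow(records))
  brk <- seq(0, 100 + bin_width, by = bin_width)
  cut0 <- function(v) pmin(floor(v / bin_width) * bin_width, 100 - bin_width)
  out <- tibble(
    group = as.character(g),
    div_bin = cut0(records$divergence),
    id_bin = cut0(records[[seed_name]])
  ) |>
    count(.data$group, .data$div_bin, .data$id_bin, name = "n")
  ov <- NULL
  if (!is.null(overlay)) {
    missing_ids <- setdiff(overlay, records$read_id)
    if (length(missing_ids) > 0) {
      warn(sprintf("%d overlay ids absent from records; skipped", length(missing_ids)))
    }
    hit <- records[records$read_id %in% overlay, , drop = FALSE]
    ov <- tibble(
      read_id = hit$read_id,
      divergence = hit$divergence,
      identity = hit[[seed_name]]
    )
  }
  attr(out, "overlay") <- ov
  attr(out, "seed_name") <- seed_name
  attr(out, "bin_width") <- bin_width
  class(out) <- c("iddiv_grid", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.iddiv_grid <- function(object, ...) {
  bw <- attr(object, "bin_width")
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$div_bin + bw / 2, y = .data$id_bin + bw / 2, fill = .data$n
  )) +
    ggplot2::geom_tile(width = bw, height = bw) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(
      x = "divergence from germline V (%)",
      y = sprintf("identity to %s (%%)", attr(object, "seed_name")),
      fill = "reads"
    ) +
    ggplot2::facet_wrap(~group)
  ov <- attr(object, "overlay")
  if (!is.null(ov) && nrow(ov) > 0) {
    p <- p + ggplot2::geom_point(
      data = ov,
      ggplot2::aes(x = .data$divergence, y = .data$identity),
      inherit.aes = FALSE, colour = "orange", size = 1
    )
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.repertoire_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$value), y = .data$n, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = attr(object, "variable"), y = "count", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# rectangular layout of a rooted phylo: tips get integer y in cladewise
# order, internal nodes the mean of their children; x is cumulative branch
# length from the root
tree_layout <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  post <- ape::reorder.phylo(phy, "postorder")
  depth <- numeric(nnode)
  pre <- post$edge[rev(seq_len(nrow(post$edge))), , drop = FALSE]
  pre_len <- rev(post$edge.length)
  for (e in seq_len(nrow(pre))) {
    depth[pre[e, 2]] <- depth[pre[e, 1]] + pre_len[e]
  }
  y <- numeric(nnode)
  clad <- ape::reorder.phylo(phy, "cladewise")
  tip_seq <- clad$edge[clad$edge[, 2] <= ntip, 2]
  y[tip_seq] <- seq_along(tip_seq)
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]
    kids <- post$edge[post$edge[, 1] == p, 2]
    y[p] <- mean(y[kids])
  }
  list(depth = depth, y = y)
}

# earliest birthday (by label order) among the NGS leaves below each node
branch_birthdays <- function(phy, birthdays, label_order) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  idx <- setNames(seq_along(label_order), label_order)
  node_bd <- rep(NA_real_, nnode)
  node_bd[seq_len(ntip)] <- idx[birthdays[phy$tip.label]]
  post <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    node_bd[p] <- min(node_bd[p], node_bd[ch], na.rm = TRUE)
    if (!is.finite(node_bd[p])) node_bd[p] <- NA_real_
  }
  ifelse(is.na(node_bd), NA_character_, label_order[node_bd])
}

#' Render a birthday-colored lineage tree
#'
#' Draws the rooted tree with every branch colored by the earliest birthday
#' among the NGS leaves below it; leaves without a birthday (germline,
#' known mAbs) are drawn grey. Returns the plot together with its legend
#' table (label -> colour), so the figure always has a machine-readable
#' twin.
#'
#' @param tree rooted `phylo` or `ontogeny_tree`.
#' @param birthdays named vector leaf id -> birthday label.
#' @param label_order labels in temporal order.
#' @param label_nodes ids of leaves/internal nodes to print labels for
#'   (unknown ids produce a warning).
#' @return list with `plot` (ggplot) and `legend` (tibble label, colour).
#' @export
render_tree <- function(tree, birthdays, label_order,
                        label_nodes = character(0)) {
  phy <- if (inherits(tree, "ontogeny_tree")) tree$tree else tree
  ntip <- length(phy$tip.label)
  lay <- tree_layout(phy)
  bd <- branch_birthdays(phy, birthdays, label_order)
  seg <- map(seq_len(nrow(phy$edge)), function(e) {
    p <- phy$edge[e, 1]
    ch <- phy$edge[e, 2]
    tibble(
      x = lay$depth[p], xend = lay$depth[ch],
      y = lay$y[ch], yend = lay$y[ch], vx = lay$depth[p],
      vy = lay$y[p], vyend = lay$y[ch],
      birthday = bd[ch]
    )
  }) |> bind_rows()
  pal <- grDevices::hcl.colors(max(length(label_order), 2), "Zissou 1")
  pal <- setNames(pal[seq_along(label_order)], label_order)
  legend <- tibble(label = label_order, colour = unname(pal[label_order]))
  all_names <- c(phy$tip.label, phy$node.label)
  unknown <- setdiff(label_nodes, all_names)
  if (length(unknown) > 0) {
    warn(sprintf("labels not in tree: %s", paste(unknown, collapse = ", ")))
  }
  lab_idx <- match(intersect(label_nodes, all_names), all_names)
  labs <- tibble(
    x = lay$depth[lab_idx], y = lay$y[lab_idx],
    label = all_names[lab_idx]
  )
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$vx, xend = .data$vx, y = .data$vy, yend = .data$vyend,
      colour = .data$birthday
    ), linewidth = 0.3) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend,
      colour = .data$birthday
    ), linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = pal, na.value = "grey40") +
    ggplot2::labs(x = "substitutions/site", y = NULL, colour = "birthday") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
  if (nrow(labs) > 0) {
    p <- p + ggplot2::geom_text(
      data = labs, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.05, size = 2.5
    )
  }
  list(plot = p, legend = legend)
}
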