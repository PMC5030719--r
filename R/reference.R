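#' Load a germline gene library from FASTA
#'
#' Parses IMGT-style pipe-delimited headers (allele name in the second field,
#' functionality class in the fourth) as well as plain `>IGHV3-30*18` headers.
#' Allele names are collapsed to genes by truncating at `*`; alleles with
#' byte-identical sequences are grouped, because such alleles (e.g.
#' IGHV3-30*18 and IGHV3-30-5*01) cannot be distinguished by alignment and
#' downstream analyses work at the gene level. Alleles annotated ORF or P
#' (pseudogene) are excluded by default.
#'
#' @param fasta_path path to a FASTA file of germline alleles.
#' @param segment one of "V", "D", "J", "C".
#' @param chain one of "heavy", "kappa", "lambda".
#' @param keep_orf_p keep ORF/pseudogene alleles (default FALSE).
#' @return a `germline_library`: a tibble with columns `allele_name`,
#'   `gene_name`, `segment`, `chain`, `sequence`, `functionality`,
#'   `duplicate_group` (integer id shared by identically-sequenced alleles),
#'   `anchor` (NA until [annotate_anchors()] is run) and `unanchored`.
#' @export
load_germline_library <- function(fasta_path, segment = c("V", "D", "J", "C"),
                                  chain = c("heavy", "kappa", "lambda"),
                                  keep_orf_p = FALSE) {
  segment <- match.arg(segment)
  chain <- match.arg(chain)
  if (!file.exists(fasta_path)) abort(sprintf("file not found: %s", fasta_path))
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0) abort(sprintf("empty germline FASTA: %s", fasta_path))
  headers <- names(set)
  parse_header <- function(h) {
    if (grepl("|", h, fixed = TRUE)) {
      f <- strsplit(h, "|", fixed = TRUE)[[1]]
      allele <- trimws(f[2])
      func <- if (length(f) >= 4) gsub("[()\\[\\] ]", "", f[4]) else "F"
    } else {
      allele <- trimws(sub("\\s.*$", "", h))
      func <- "F"
    }
    if (!nzchar(func)) func <- "F"
    c(allele, func)
  }
  parsed <- unname(t(vapply(headers, parse_header, character(2))))
  lib <- tibble(
    allele_name = parsed[, 1],
    functionality = parsed[, 2],
    sequence = normalize_dna(as.character(set), names = parsed[, 1])
  )
  if (!keep_orf_p) {
    lib <- filter(lib, !.data$functionality %in% c("ORF", "P"))
    if (nrow(lib) == 0) abort("no functional alleles left after ORF/P filtering")
  }
  # duplicate names: identical sequences collapse silently, conflicts error
  conf <- lib |>
    group_by(.data$allele_name) |>
    summarise(n_seq = dplyr::n_distinct(.data$sequence), .groups = "drop") |>
    filter(.data$n_seq > 1)
  if (nrow(conf) > 0) {
    abort(sprintf(
      "allele '%s' appears multiple times with differing sequences",
      conf$allele_name[1]
    ))
  }
  lib <- dplyr::distinct(lib, .data$allele_name, .keep_all = TRUE)
  lib <- lib |>
    mutate(
      gene_name = sub("\\*.*$", "", .data$allele_name),
      segment = segment,
      chain = chain,
      duplicate_group = as.integer(factor(.data$sequence,
        levels = unique(.data$sequence)
      )),
      anchor = NA_integer_,
      unanchored = NA
    ) |>
    select(
      "allele_name", "gene_name", "segment", "chain", "sequence",
      "functionality", "duplicate_group", "anchor", "unanchored"
    ) |>
    arrange(.data$allele_name)
  class(lib) <- c("germline_library", class(lib))
  lib
}

#' Duplicate groups of a germline library
#'
#' @param lib a `germline_library`.
#' @return list of character vectors of allele names; alleles listed together
#'   have identical sequences.
#' @export
duplicate_groups <- function(lib) {
  unname(split(lib$allele_name, lib$duplicate_group))
}

#' Write a germline library back to FASTA
#'
#' @param lib a `germline_library`.
#' @param path output path.
#' @export
write_germline_library <- function(lib, path) {
  write_fasta(lib, path, id = "allele_name", seq = "sequence")
}

# last in-frame TGT/TGC within the final 12 codons (frame 0 of the V)
find_v_anchor <- function(seq) {
  L <- nchar(seq)
  starts <- seq.int(0L, L - 3L, by = 3L)
  starts <- starts[starts >= L - 36L]
  codons <- substring(seq, starts + 1L, starts + 3L)
  hit <- which(codons %in% c("TGT", "TGC"))
  if (length(hit) == 0) return(NA_integer_)
  starts[max(hit)]
}

# first W/F-G-X-G motif: codon1 in {TGG,TTT,TTC}, codons 2 and 4 start "GG"
find_j_anchor <- function(seq) {
  L <- nchar(seq)
  if (L < 12) return(NA_integer_)
  for (p in 0:(L - 12L)) {
    c1 <- substr(seq, p + 1L, p + 3L)
    if (!(c1 %in% c("TGG", "TTT", "TTC"))) next
    if (substr(seq, p + 4L, p + 5L) != "GG") next
    if (substr(seq, p + 10L, p + 11L) != "GG") next
    return(p)
  }
  NA_integer_
}

#' Annotate CDR3 anchor positions on V and J alleles
#'
#' For each V allele, records the 0-based offset of the codon of the second
#' conserved cysteine (IMGT position 104), found as the last in-frame TGT/TGC
#' within the final 12 codons. For each J allele, records the offset of the
#' first codon of the conserved W/F-G-X-G motif (IMGT 118). Alleles where no
#' anchor is found are flagged `unanchored`; they stay in the library for
#' gene assignment but are excluded from CDR3 extraction.
#'
#' @param lib a `germline_library` (any segment; only V and J rows gain
#'   anchors).
#' @return the library with `anchor` and `unanchored` filled in.
#' @export
annotate_anchors <- function(lib) {
  lib <- mutate(lib,
    anchor = dplyr::case_when(
      .data$segment == "V" ~ map_int(.data$sequence, find_v_anchor),
      .data$segment == "J" ~ map_int(.data$sequence, find_j_anchor),
      TRUE ~ NA_integer_
    ),
    unanchored = .data$segment %in% c("V", "J") & is.na(.data$anchor)
  )
  class(lib) <- unique(c("germline_library", class(lib)))
  lib
}
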