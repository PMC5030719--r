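#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n desc across all_of count rename
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap keep
#' @importFrom stats optimize setNames runif rbinom
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, strips gap characters ("-", "."), and
#' validates that only A, C, G, T, N remain.
#'
#' @param x character vector of sequences.
#' @param names optional record names used in error messages.
#' @return normalized character vector.
#' @export
normalize_dna <- function(x, names = NULL) {
  out <- toupper(x)
  out <- gsub("U", "T", out, fixed = TRUE)
  out <- gsub("[.\\-]", "", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    lab <- if (!is.null(names)) names[which(bad)[1]] else which(bad)[1]
    abort(sprintf(
      "record '%s' contains characters outside A,C,G,T,N after normalization",
      lab
    ))
  }
  unname(out)
}

#' Read sequences into a tibble
#'
#' Reads FASTA or FASTQ (auto-detected from the file extension, falling back
#' to sniffing the first character) into a two-column tibble. Qualities in
#' FASTQ input are parsed and discarded.
#'
#' @param path file path.
#' @return tibble with columns `read_id`, `sequence`.
#' @export
read_seqs <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  is_fastq <- grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)
  if (!grepl("\\.(fa|fasta|fna|fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    first <- substr(readLines(path, n = 1L), 1, 1)
    is_fastq <- identical(first, "@")
  }
  set <- if (is_fastq) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  if (length(set) == 0) abort(sprintf("no sequences in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  tibble(read_id = ids, sequence = as.character(set))
}

#' Write sequences to FASTA
#'
#' @param x tibble with id and sequence columns, or a named character vector.
#' @param path output path.
#' @param id,seq column names used when `x` is a data frame.
#' @param width line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, id = "read_id", seq = "sequence", width = 80) {
  if (is.data.frame(x)) {
    seqs <- setNames(x[[seq]], x[[id]])
  } else {
    seqs <- x
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- setNames(as.character(gc), names(gc))
    }
    tab
  }
})

#' Translate nucleotides to amino acids
#'
#' Standard-code translation in frame 0; a trailing partial codon is
#' dropped; codons containing N translate to `X`; stop codons appear as `*`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(x) {
  tab <- codon_table()
  vapply(x, function(s) {
    L <- 3 * (nchar(s) %/% 3)
    if (L == 0) return("")
    codons <- substring(s, seq(1, L, 3), seq(3, L, 3))
    aa <- tab[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# derive a stream of sub-seeds from one user seed, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
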