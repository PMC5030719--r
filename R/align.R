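#' Alignment parameters
#'
#' Scoring scheme and acceptance thresholds for the pairwise alignment engine.
#' Defaults follow BLASTN-like nucleotide scoring: match +5, mismatch -4,
#' affine gaps with opening cost 8 and extension cost 2 per gap column. A V
#' hit is accepted when its score reaches `min_score_v` and the aligned
#' reference span covers at least `min_cover_v` of the V allele; J hits need
#' `min_score_j`; D hits need `min_score_d` (25 = five consecutive matches).
#' The V default of 250 sits well above the ~160-190 that gapped chaining of
#' chance matches attains on unrelated 400-nt sequences under this scoring,
#' and far below genuine V hits (>= ~700 even at 25% divergence).
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap costs (positive numbers).
#' @param min_score_v,min_cover_v,min_score_j,min_score_d,min_score_c
#'   acceptance thresholds per segment.
#' @return a list of class `align_params`.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = 8, gap_extend = 2,
                         min_score_v = 250, min_cover_v = 0.5,
                         min_score_j = 30, min_score_d = 25,
                         min_score_c = 30) {
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_open = gap_open, gap_extend = gap_extend,
      min_score_v = min_score_v, min_cover_v = min_cover_v,
      min_score_j = min_score_j, min_score_d = min_score_d,
      min_score_c = min_score_c
    ),
    class = "align_params"
  )
}

# vectorized score-only alignment of many patterns against one subject
aln_scores <- function(patterns, subject, params, type = "local") {
  .align_scores_cpp(
    as.character(patterns), subject, type,
    params$match, params$mismatch, params$gap_open, params$gap_extend
  )
}

# detailed pairwise alignment; intervals are returned 0-based half-open
aln_detail <- function(pattern, subject, params, type = "local") {
  .align_pair_cpp(
    pattern, subject, type,
    params$match, params$mismatch, params$gap_open, params$gap_extend
  )
}

# detailed alignment of many patterns against one subject
aln_detail_batch <- function(patterns, subject, params, type = "local") {
  lapply(patterns, aln_detail, subject = subject, params = params, type = type)
}

# map 0-based subject (reference) positions to 0-based pattern (read)
# positions through an alignment detail; positions aligned to a gap, or
# outside the aligned interval, map to NA
ref_to_read_map <- function(d) {
  p <- strsplit(d$pat_aln, "")[[1]]
  s <- strsplit(d$sub_aln, "")[[1]]
  ref_pos <- d$sub_start
  read_pos <- d$pat_start
  map <- rep(NA_integer_, d$sub_end - d$sub_start)
  for (k in seq_along(p)) {
    if (s[k] != "-" && p[k] != "-") {
      map[ref_pos - d$sub_start + 1L] <- read_pos
    }
    if (s[k] != "-") ref_pos <- ref_pos + 1L
    if (p[k] != "-") read_pos <- read_pos + 1L
  }
  map
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch alignment under the engine's scoring scheme; identity is
#' matches divided by total alignment columns, so gap columns (including end
#' gaps) count as mismatches.
#'
#' @param a,b nucleotide sequences.
#' @param params [align_params()].
#' @return identity as a fraction in \[0, 1\].
#' @export
global_identity <- function(a, b, params = align_params()) {
  d <- aln_detail(a, b, params, type = "global")
  d$matches / d$columns
}

# identity and divergence helpers returning percentages
global_pct_identity <- function(a, b, params = align_params()) {
  100 * global_identity(a, b, params)
}
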