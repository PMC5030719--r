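STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

sample_codons <- function(n, exclude = STOP_CODONS) {
  pool <- setdiff(all_codons(), exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

rand_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-repertoire generator:
#' germline library size, lineage structure over time points, somatic
#' hypermutation (SHM) accumulation per time step, V(D)J junction geometry
#' (exonuclease chewback and non-templated N insertions), and a
#' pyrosequencing-style error layer (substitutions plus rare 1-nt indels).
#'
#' @param rng_seed integer seed; required, all randomness derives from it.
#' @param n_v,n_d,n_j,n_c number of germline genes per segment.
#' @param n_lineages number of expanded clonal lineages.
#' @param lineage_sizes reads sampled per lineage at each time point
#'   (recycled across lineages).
#' @param n_background unrelated singleton-lineage reads per time point.
#' @param shm_rate expected substitutions/site accumulated per time step
#'   within a lineage.
#' @param background_shm_max background reads carry SHM drawn uniformly from
#'   0 to this rate.
#' @param hotspot double the mutation weight on WRC/GYW hotspot motifs.
#' @param carryover_prob probability a lineage read at time t is an exact
#'   resampling of a time t-1 read (drives multi-time-point observations).
#' @param sub_error_rate per-base sequencing substitution probability.
#' @param indel_rate per-read probability of a single 1-nt sequencing indel.
#' @param chewback_max maximum nucleotides chewed back per junction side.
#' @param n_insert_max maximum non-templated nucleotides per junction side.
#' @param cdr3_len_aa optional fixed CDR3 (junction) length in amino acids;
#'   when NULL, junction length follows from chewback/insertion draws
#'   constrained to keep the junction in frame.
#' @param timepoints ordered character labels of the sampling time points.
#' @param background_same_v force background reads onto the first lineage's
#'   V allele (used to stress seeded-lineage discrimination).
#' @param include_c append a constant-region fragment (first `c_frag_len` nt
#'   of a random C gene) after the J segment.
#' @param c_frag_len length of the appended constant fragment.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(rng_seed,
                       n_v = 8, n_d = 6, n_j = 4, n_c = 2,
                       n_lineages = 1,
                       lineage_sizes = c(20, 25, 30),
                       n_background = c(60, 60, 60),
                       shm_rate = 0.05,
                       background_shm_max = 0.05,
                       hotspot = TRUE,
                       carryover_prob = 0.2,
                       sub_error_rate = 0,
                       indel_rate = 0,
                       chewback_max = 5,
                       n_insert_max = 8,
                       cdr3_len_aa = NULL,
                       timepoints = c("wk08", "wk34", "wk59"),
                       background_same_v = FALSE,
                       include_c = TRUE,
                       c_frag_len = 45) {
  if (missing(rng_seed)) abort("rng_seed is required")
  stopifnot(
    n_v >= 1, n_j >= 1, n_d >= 0, n_lineages >= 0,
    shm_rate >= 0, shm_rate <= 1,
    sub_error_rate >= 0, sub_error_rate <= 1,
    indel_rate >= 0, indel_rate <= 1,
    chewback_max >= 0, n_insert_max >= 2,
    length(timepoints) >= 1, !anyDuplicated(timepoints)
  )
  lineage_sizes <- rep_len(as.integer(lineage_sizes), length(timepoints))
  n_background <- rep_len(as.integer(n_background), length(timepoints))
  structure(
    list(
      rng_seed = as.integer(rng_seed),
      n_v = n_v, n_d = n_d, n_j = n_j, n_c = n_c,
      n_lineages = n_lineages,
      lineage_sizes = lineage_sizes, n_background = n_background,
      shm_rate = shm_rate, background_shm_max = background_shm_max,
      hotspot = hotspot, carryover_prob = carryover_prob,
      sub_error_rate = sub_error_rate, indel_rate = indel_rate,
      chewback_max = chewback_max, n_insert_max = n_insert_max,
      cdr3_len_aa = cdr3_len_aa,
      timepoints = timepoints,
      background_same_v = background_same_v,
      include_c = include_c, c_frag_len = c_frag_len
    ),
    class = "sim_config"
  )
}

make_v_allele <- function() {
  # 96 codons + TGT (Cys-104 anchor at offset 288) + 5-nt tail; the last 12
  # in-frame codons other than the anchor avoid TGT/TGC so the anchor is
  # unambiguous, and the whole gene is stop-free in frame 0
  body <- paste0(
    sample_codons(87),
    sample_codons(9, exclude = c(STOP_CODONS, "TGT", "TGC"))
  )
  paste0(body, "TGT", "GCGAG")
}

make_j_allele <- function() {
  repeat {
    head <- rand_nt(18)
    motif <- paste0(
      "TGG",
      paste0("GG", sample(c("A", "C", "G", "T"), 1)),
      sample_codons(1),
      paste0("GG", sample(c("A", "C", "G", "T"), 1))
    )
    tail <- sample_codons(6)
    seq <- paste0(head, motif, tail)
    if (identical(find_j_anchor(seq), 18L)) return(seq)
  }
}

#' Generate a synthetic germline gene library
#'
#' Builds random but structurally realistic heavy-chain V, D, J, and C
#' references: V alleles of 296 nt ending in a conserved-cysteine codon
#' context, J alleles of 48 nt containing a W-G-X-G motif, D alleles of
#' 10-25 nt, and short constant-region fragments. A subset of genes gets a
#' second allele differing by 1-2 substitutions. Deterministic under
#' `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return a `germline_library` tibble covering all segments.
#' @export
make_germline <- function(config) {
  withr::with_seed(derive_seed(config$rng_seed, 1L), {
    mk <- function(n, segment, prefix, maker) {
      if (n == 0) return(NULL)
      genes <- sprintf("%s%d-%d", prefix, ((seq_len(n) - 1) %% 7) + 1, seq_len(n))
      rows <- map(seq_len(n), function(i) {
        s1 <- maker()
        out <- tibble(
          allele_name = paste0(genes[i], "*01"), gene_name = genes[i],
          segment = segment, chain = "heavy", sequence = s1,
          functionality = "F"
        )
        if (segment == "V" && i <= ceiling(n / 4)) {
          # second allele: 1-2 substitutions outside the anchor region
          s2 <- strsplit(s1, "")[[1]]
          pos <- sample(seq_len(250), sample(1:2, 1))
          for (p in pos) s2[p] <- sample(setdiff(c("A", "C", "G", "T"), s2[p]), 1)
          out <- bind_rows(out, mutate(out[1, ],
            allele_name = paste0(genes[i], "*02"),
            sequence = paste(s2, collapse = "")
          ))
        }
        out
      })
      bind_rows(rows)
    }
    lib <- bind_rows(
      mk(config$n_v, "V", "IGHV", make_v_allele),
      mk(config$n_d, "D", "IGHD", function() rand_nt(sample(10:25, 1))),
      mk(config$n_j, "J", "IGHJ", make_j_allele),
      mk(config$n_c, "C", "IGHC", function() sample_codons(25))
    )
    lib <- lib |>
      group_by(.data$segment) |>
      mutate(duplicate_group = as.integer(factor(.data$sequence,
        levels = unique(.data$sequence)
      ))) |>
      ungroup() |>
      mutate(anchor = NA_integer_, unanchored = NA)
    class(lib) <- c("germline_library", class(lib))
    annotate_anchors(lib)
  })
}

lib_segment <- function(lib, segment) {
  out <- lib[lib$segment == segment, , drop = FALSE]
  if (nrow(out) == 0) abort(sprintf("library has no %s segment", segment))
  out
}

mutate_seq <- function(seq, n_mut, hotspot = TRUE) {
  if (n_mut <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  w <- rep(1, length(chars))
  if (hotspot) {
    # WRC / GYW AID hotspots get double weight on the central position
    s <- paste(chars, collapse = "")
    for (m in gregexpr("[AT][AG]C", s)[[1]]) if (m > 0) w[m + 2] <- 2
    for (m in gregexpr("G[CT][AT]", s)[[1]]) if (m > 0) w[m] <- 2
  }
  n_mut <- min(n_mut, length(chars))
  pos <- sample(seq_along(chars), n_mut, prob = w)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) abort("hamming on unequal lengths")
  sum(x != y)
}

# one V(D)J recombination event; returns the naive sequence plus truth
recombine <- function(config, vrow, drow, jrow) {
  v_seq <- vrow$sequence
  v_len <- nchar(v_seq)
  cys <- vrow$anchor
  tail_len <- v_len - (cys + 3L)
  j_seq <- jrow$sequence
  j_off <- jrow$anchor
  tries <- 0L
  repeat {
    tries <- tries + 1L
    cv <- sample(0:min(config$chewback_max, tail_len), 1)
    cj <- sample(0:min(config$chewback_max, j_off), 1)
    d_seq <- if (!is.null(drow)) drow$sequence else ""
    if (nchar(d_seq) > 0) {
      cd1 <- sample(0:min(config$chewback_max, nchar(d_seq) - 1), 1)
      cd2 <- sample(0:min(config$chewback_max, nchar(d_seq) - 1 - cd1), 1)
      d_used <- substr(d_seq, cd1 + 1, nchar(d_seq) - cd2)
    } else {
      d_used <- ""
    }
    t1 <- tail_len - cv
    jh <- j_off - cj
    base <- t1 + nchar(d_used) + jh
    if (!is.null(config$cdr3_len_aa)) {
      needed <- 3L * config$cdr3_len_aa - base
      if (needed < 0) next
      n1 <- needed %/% 2L
      n2 <- needed - n1
    } else {
      n1 <- sample(0:config$n_insert_max, 1)
      ok_n2 <- (0:config$n_insert_max)[(base + n1 + 0:config$n_insert_max) %% 3 == 0]
      n2 <- if (length(ok_n2) == 1) ok_n2 else sample(ok_n2, 1)
    }
    v_used <- substr(v_seq, 1, v_len - cv)
    j_used <- substr(j_seq, cj + 1, nchar(j_seq))
    junction <- paste0(
      substr(v_used, cys + 4L, nchar(v_used)),
      rand_nt(n1), d_used, rand_nt(n2),
      substr(j_used, 1, jh)
    )
    # naive receptors are productive: redraw junctions with in-frame stops,
    # then (some D/J pairs make stop-free draws rare) patch remaining stop
    # codons by setting their third base to C
    codons <- substring(junction, seq(1, nchar(junction), 3),
                        seq(3, nchar(junction) + 2, 3))
    if (any(codons %in% STOP_CODONS) && tries < 20L) next
    if (any(codons %in% STOP_CODONS)) {
      codons[codons %in% STOP_CODONS] <- paste0(
        substr(codons[codons %in% STOP_CODONS], 1, 2), "C"
      )
      junction <- paste(codons, collapse = "")
    }
    seq <- paste0(
      substr(v_used, 1, cys + 3L),
      junction,
      substr(j_used, jh + 1L, nchar(j_used))
    )
    # SHM is substitution-only, so junction coordinates stay valid in all
    # descendants of this recombination event
    return(list(
      sequence = seq, junction = junction,
      junc_start = cys + 3L, junc_len = nchar(junction)
    ))
  }
}

apply_seq_error <- function(seq, config) {
  n_sub <- rbinom(1, nchar(seq), config$sub_error_rate)
  if (n_sub > 0) seq <- mutate_seq(seq, n_sub, hotspot = FALSE)
  has_indel <- runif(1) < config$indel_rate
  if (has_indel) {
    p <- sample(nchar(seq), 1)
    if (runif(1) < 0.5) {
      seq <- paste0(substr(seq, 1, p), rand_nt(1), substr(seq, p + 1, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1, p - 1), substr(seq, p + 1, nchar(seq)))
    }
  }
  list(sequence = seq, has_indel = has_indel)
}

#' Simulate a longitudinal BCR repertoire with recorded ground truth
#'
#' Per lineage, a naive V(D)J recombination event is drawn and the clone
#' expands over the configured time points, accumulating SHM at `shm_rate`
#' per step (with optional WRC/GYW hotspot weighting); some reads are exact
#' carryovers of the previous time point. Unrelated background reads are
#' drawn as singleton lineages. A sequencing layer then adds substitution
#' errors and rare 1-nt indels. Everything is recorded in a truth table.
#'
#' @param config a [sim_config()].
#' @param lib germline library from [make_germline()] (one is generated from
#'   the config when omitted).
#' @return list with `reads` (tibble: timepoint, read_id, sequence), `truth`
#'   (tibble: read_id, timepoint, lineage_id, v_allele, d_allele, j_allele,
#'   junction_nt, n_shm, has_artifact_indel, is_background,
#'   first_timepoint), `lib`, and `config`.
#' @export
simulate_repertoire <- function(config, lib = make_germline(config)) {
  vlib <- lib_segment(lib, "V")
  jlib <- lib_segment(lib, "J")
  dlib <- if (any(lib$segment == "D")) lib_segment(lib, "D") else NULL
  clib <- if (config$include_c && any(lib$segment == "C")) lib_segment(lib, "C") else NULL
  withr::with_seed(derive_seed(config$rng_seed, 2L), {
    counter <- 0L
    rows <- list()
    emit <- function(tp, lineage_id, seq0, truth) {
      counter <<- counter + 1L
      err <- apply_seq_error(seq0, config)
      rows[[counter]] <<- tibble(
        read_id = sprintf("R%06d", counter),
        timepoint = tp, lineage_id = lineage_id,
        sequence = err$sequence,
        clean_sequence = seq0,
        v_allele = truth$v, d_allele = truth$d, j_allele = truth$j,
        junction_nt = substr(seq0, truth$junc_start + 1L,
                             truth$junc_start + truth$junc_len),
        n_shm = truth$n_shm,
        has_artifact_indel = err$has_indel,
        is_background = truth$background
      )
    }
    pick <- function(l) l[sample(nrow(l), 1), , drop = FALSE]
    with_c <- function(seq) {
      if (is.null(clib)) return(seq)
      crow <- pick(clib)
      paste0(seq, substr(crow$sequence, 1, config$c_frag_len))
    }
    for (ln in seq_len(config$n_lineages)) {
      vrow <- pick(vlib)
      jrow <- pick(jlib)
      drow <- if (!is.null(dlib)) pick(dlib) else NULL
      rec <- recombine(config, vrow, drow, jrow)
      naive <- with_c(rec$sequence)
      truth0 <- list(
        v = vrow$allele_name, j = jrow$allele_name,
        d = if (!is.null(drow)) drow$allele_name else NA_character_,
        junc_start = rec$junc_start, junc_len = rec$junc_len,
        background = FALSE
      )
      # by the first sampled visit the expanded clone has already accumulated
      # one round of SHM shared by all its members (the lineage signature)
      pool <- mutate_seq(
        naive, rbinom(1, nchar(naive), config$shm_rate),
        hotspot = config$hotspot
      )
      for (ti in seq_along(config$timepoints)) {
        tp <- config$timepoints[ti]
        sampled <- character(0)
        for (k in seq_len(config$lineage_sizes[ti])) {
          if (ti > 1 && runif(1) < config$carryover_prob) {
            seq0 <- sample(pool, 1)
          } else {
            parent <- sample(pool, 1)
            m <- rbinom(1, nchar(parent), config$shm_rate)
            seq0 <- mutate_seq(parent, m, hotspot = config$hotspot)
          }
          sampled <- c(sampled, seq0)
          t0 <- truth0
          t0$n_shm <- hamming(seq0, naive)
          emit(tp, sprintf("L%02d", ln), seq0, t0)
        }
        if (length(sampled) > 0) pool <- sampled
      }
    }
    bg_v <- if (config$background_same_v && config$n_lineages >= 1) {
      rows[[1]]$v_allele
    } else {
      NA_character_
    }
    for (ti in seq_along(config$timepoints)) {
      tp <- config$timepoints[ti]
      for (k in seq_len(config$n_background[ti])) {
        vrow <- if (!is.na(bg_v)) {
          vlib[vlib$allele_name == bg_v, , drop = FALSE]
        } else {
          pick(vlib)
        }
        jrow <- pick(jlib)
        drow <- if (!is.null(dlib)) pick(dlib) else NULL
        rec <- recombine(config, vrow, drow, jrow)
        seq0 <- with_c(rec$sequence)
        m <- rbinom(1, nchar(seq0), runif(1, 0, config$background_shm_max))
        mut <- mutate_seq(seq0, m, hotspot = config$hotspot)
        emit(tp, sprintf("B%06d", counter + 1L), mut, list(
          v = vrow$allele_name, j = jrow$allele_name,
          d = if (!is.null(drow)) drow$allele_name else NA_character_,
          junc_start = rec$junc_start, junc_len = rec$junc_len,
          background = TRUE, n_shm = m
        ))
      }
    }
    truth <- bind_rows(rows)
    tp_index <- setNames(seq_along(config$timepoints), config$timepoints)
    truth <- truth |>
      group_by(.data$sequence) |>
      mutate(first_timepoint = config$timepoints[min(tp_index[.data$timepoint])]) |>
      ungroup()
    list(
      reads = select(truth, "timepoint", "read_id", "sequence"),
      truth = select(
        truth, "read_id", "timepoint", "lineage_id", "v_allele",
        "d_allele", "j_allele", "junction_nt", "n_shm",
        "has_artifact_indel", "is_background", "first_timepoint",
        "sequence", "clean_sequence"
      ),
      lib = lib, config = config
    )
  })
}

#' Write a simulated repertoire to disk
#'
#' One FASTA per time point plus a tab-separated truth table.
#'
#' @param sim result of [simulate_repertoire()].
#' @param dir output directory (created if needed).
#' @return named character vector of FASTA paths (by time-point label),
#'   invisibly.
#' @export
write_repertoire <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$config$timepoints, function(tp) {
    p <- file.path(dir, paste0(tp, ".fasta"))
    write_fasta(filter(sim$reads, .data$timepoint == tp), p)
    p
  }, character(1))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(paths)
}
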