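# Synthetic regulatory-sequence simulator: i.i.d. background of configurable
# GC content with planted site arrangements of each grammar tier, decoy
# sites, machine-readable truth labels, and recovery scoring.
#
# The generator is the package's no-download test bed: with decoy_density 0
# it guarantees that the only motif matches in a sequence are the planted
# ones (spurious background matches are resampled away), so site recall and
# tier accuracy over a batch are exactly measurable.

ARRANGEMENTS <- c("FULL_DIRECT", "FULL_MIRROR", "PARTIAL_INVERTED",
                  "ORIENT_VIOLATION", "SPAN_VIOLATION", "INCOMPLETE",
                  "BACKGROUND_ONLY")

# Tier each arrangement is constructed to produce (re-derived, not assumed,
# at generation time by running the grammar evaluator on the truth).
ARRANGEMENT_TIER <- c(
  FULL_DIRECT = "SFZE_FULL", FULL_MIRROR = "SFZE_FULL",
  PARTIAL_INVERTED = "SFZE_LIKE_INVERTED",
  ORIENT_VIOLATION = "SFZE_LIKE_ORIENT",
  SPAN_VIOLATION = "SFZE_LIKE_SPAN",
  INCOMPLETE = "INCOMPLETE", BACKGROUND_ONLY = "INCOMPLETE")

#' Simulation configuration
#'
#' @param seed global seed; each sequence draws from a deterministic
#'   substream mixed from this seed and the sequence index.
#' @param n_sequences number of sequences.
#' @param length sequence length in bp (default 700, the scale of real
#'   CRMs).
#' @param gc_content GC fraction in (0,1]; G and C split equally, as do A
#'   and T.
#' @param arrangement one of `"FULL_DIRECT"`, `"FULL_MIRROR"`,
#'   `"PARTIAL_INVERTED"`, `"ORIENT_VIOLATION"`, `"SPAN_VIOLATION"`,
#'   `"INCOMPLETE"`, `"BACKGROUND_ONLY"`, or a vector of these recycled
#'   over the sequences (a mixed-tier batch).
#' @param n_f_sites number of Foxh1 sites to plant (1 or 2).
#'   `SPAN_VIOLATION` always plants a single Foxh1 site: with two, a
#'   narrower fully compliant sub-arrangement would exist and the intended
#'   tier would not be well defined.
#' @param decoy_density expected decoy consensus matches per kb (Poisson).
#' @param plant_score_floor minimum relative score for matrix-sampled
#'   plants (default 0.9).
#' @param core_span_range optional `c(min, max)` target range for the
#'   Foxh1-Zic-Ets core span; defaults to at most `max_core_span` for
#'   compliant arrangements and `(max_core_span, max_core_span + 113]` for
#'   `SPAN_VIOLATION`. The range must be consistent with the arrangement.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_sequences = 1L, length = 700L,
                              gc_content = 0.4, arrangement = "FULL_DIRECT",
                              n_f_sites = 2L, decoy_density = 0,
                              plant_score_floor = 0.9,
                              core_span_range = NULL) {
  stopifnot(n_sequences >= 1L, length >= 50L,
            gc_content > 0, gc_content <= 1,
            n_f_sites %in% c(1L, 2L), decoy_density >= 0,
            plant_score_floor >= 0, plant_score_floor <= 1)
  arrangement <- vapply(arrangement, match.arg, character(1),
                        choices = ARRANGEMENTS)
  structure(list(seed = as.integer(seed),
                 n_sequences = as.integer(n_sequences),
                 length = as.integer(length), gc_content = gc_content,
                 arrangement = unname(arrangement),
                 n_f_sites = as.integer(n_f_sites),
                 decoy_density = decoy_density,
                 plant_score_floor = plant_score_floor,
                 core_span_range = core_span_range),
            class = "simulation_config")
}

#' Sample i.i.d. background sequences
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_content/2` and
#' `P(A) = P(T) = (1 - gc_content)/2`, one deterministic substream per
#' sequence.
#'
#' @param cfg a [simulation_config()] object.
#' @return character vector of `cfg$n_sequences` sequences.
#' @export
sample_background <- function(cfg) {
  vapply(seq_len(cfg$n_sequences), function(i) {
    set.seed(mix_seed(cfg$seed, i))
    draw_background(cfg$length, cfg$gc_content)
  }, character(1))
}

# Draws from the current RNG stream.
draw_background <- function(length, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Sample a sequence realisation of a motif
#'
#' For a consensus motif, each position is drawn uniformly from its IUPAC
#' set (a uniform draw over the consensus expansion). For a matrix motif,
#' each position is drawn from the column's normalized frequencies,
#' rejection-sampled until the relative log-odds score reaches `floor`.
#'
#' @param m a `motif_model`.
#' @param floor minimum relative score for matrix draws (default 0.9).
#' @param params a [scoring_params()] object (scoring for the floor check).
#' @param max_attempts rejection-sampling bound (default 10000).
#' @return DNA string of the motif's length.
#' @export
sample_site_sequence <- function(m, floor = 0.9, params = scoring_params(),
                                 max_attempts = 10000L) {
  if (m$model_kind == "CONSENSUS") {
    codes <- seq_chars(m$consensus)
    return(paste(vapply(codes, function(cd) {
      s <- IUPAC_SETS[[cd]]
      s[sample.int(length(s), 1L)]
    }, character(1)), collapse = ""))
  }
  wm <- build_weight_matrix(m, params)
  probs <- sweep(m$matrix, 2, colSums(m$matrix), "/")
  for (attempt in seq_len(max_attempts)) {
    word <- paste(vapply(seq_len(ncol(probs)), function(j) {
      sample(DNA_BASES, 1L, prob = probs[, j])
    }, character(1)), collapse = "")
    if (relative_score(word, wm) >= floor) return(word)
  }
  stop("motif '", m$motif_id, "': could not reach score floor ", floor,
       " in ", max_attempts, " attempts")
}

# Layout of one arrangement: classes and strands 5' to 3'. The Su(H) site
# sits on the 5' flank of the core in the direct reading and on the 3'
# flank in the mirrored reading (either flank is grammatical; one is
# enough).
arrangement_layout <- function(arrangement, n_f) {
  fplus <- rep("F", n_f)
  switch(arrangement,
    FULL_DIRECT = list(cls = c("S", fplus, "Z", "E"),
                       strand = c("+", rep("+", n_f), "+", "-")),
    FULL_MIRROR = list(cls = c("E", "Z", fplus, "S"),
                       strand = c("+", "-", rep("-", n_f), "-")),
    PARTIAL_INVERTED = list(cls = c("S", "E", "Z", fplus),
                            strand = c("+", "+", "-", rep("-", n_f))),
    ORIENT_VIOLATION = list(cls = c("S", fplus, "Z", "E"),
                            strand = c("+", rep("+", n_f), "+", "+")),
    # A second Foxh1 site would admit a narrower compliant sub-arrangement
    # and the intended tier would no longer be well defined, so span
    # violations are planted with a single Foxh1 site.
    SPAN_VIOLATION = list(cls = c("S", "F", "Z", "E"),
                          strand = c("+", "+", "+", "-")),
    INCOMPLETE = list(cls = c("S", fplus, "E"),
                      strand = c("+", rep("+", n_f), "-")),
    BACKGROUND_ONLY = list(cls = character(), strand = character()),
    stop("unknown arrangement: ", arrangement)
  )
}

pick_motif <- function(motifs, cls) {
  for (m in motifs) if (m$tf_class == cls) return(m)
  stop("no motif of class '", cls, "' in the motif set")
}

default_span_range <- function(arrangement, grammar, min_span) {
  if (arrangement == "SPAN_VIOLATION") {
    c(grammar$max_core_span + 1, grammar$max_core_span + 113)
  } else {
    c(min_span, grammar$max_core_span)
  }
}

#' Plant a site arrangement into a background sequence
#'
#' Samples site realisations, inter-site gaps within the span budget, and a
#' random offset; writes the sites into the sequence; re-derives the
#' intended tier by running the grammar evaluator on the planted geometry
#' (generation-time self-check, so the simulator and the classifier cannot
#' drift apart); then resamples any background window that happens to match
#' a motif, so that with no decoys the sequence's detectable sites are
#' exactly the planted ones. Draws from the current RNG stream.
#'
#' @param seq background DNA string.
#' @param arrangement one of the arrangement names (see
#'   [simulation_config()]).
#' @param cfg a [simulation_config()] object.
#' @param grammar a [syntax_grammar()] object.
#' @param motifs motif set used for planting and for the spurious-match
#'   scrub (see [synthetic_motif_set()]).
#' @param params a [scoring_params()] object.
#' @param seq_id identifier for the truth record.
#' @return list with `sequence` (modified string) and `truth`, an object of
#'   class `truth_record`: planted `sites` data.frame, `decoys` data.frame,
#'   `tier`, `flags`, `arrangement` label.
#' @export
plant_arrangement <- function(seq, arrangement, cfg, grammar = syntax_grammar(),
                              motifs = synthetic_motif_set(),
                              params = scoring_params(), seq_id = "synth") {
  n <- nchar(seq)
  lay <- arrangement_layout(arrangement, cfg$n_f_sites)
  if (!length(lay$cls)) {
    truth <- truth_record(seq_id, empty_sites(), empty_sites(), arrangement,
                          grammar)
    return(scrub_background(seq, truth, motifs, params, grammar))
  }
  widths <- vapply(lay$cls, function(cl) motif_length(pick_motif(motifs, cl)),
                   integer(1))
  core_pos <- which(lay$cls %in% CORE_CLASSES)
  n_core_gaps <- length(core_pos) - 1L
  min_span <- sum(widths[core_pos]) + n_core_gaps
  span_range <- cfg$core_span_range %||%
    default_span_range(arrangement, grammar, min_span)
  if (span_range[1] < min_span) span_range[1] <- min_span
  if (span_range[2] < span_range[1]) {
    stop("core span range [", span_range[1], ",", span_range[2],
         "] cannot fit ", length(core_pos), " core sites of total width ",
         sum(widths[core_pos]))
  }
  if (arrangement == "SPAN_VIOLATION") {
    if (span_range[1] <= grammar$max_core_span) {
      stop("SPAN_VIOLATION requires a core span above ",
           grammar$max_core_span)
    }
  } else if (length(core_pos) == length(CORE_CLASSES) + cfg$n_f_sites - 1L &&
             span_range[2] > grammar$max_core_span) {
    stop("compliant arrangements require a core span of at most ",
         grammar$max_core_span)
  }

  # Core gaps: >= 1 bp each, summing to (target span - total core width).
  target <- if (span_range[2] > span_range[1]) {
    sample(span_range[1]:span_range[2], 1L)
  } else {
    span_range[1]
  }
  extra <- target - sum(widths[core_pos]) - n_core_gaps
  gaps_core <- rep(1L, max(n_core_gaps, 0L))
  if (n_core_gaps > 0L && extra > 0L) {
    gaps_core <- gaps_core + tabulate(sample.int(n_core_gaps, extra,
                                                 replace = TRUE),
                                      n_core_gaps)
  }
  # Flank gap between the Su(H) site and the core.
  flank_gap <- sample(2:30, 1L)
  gaps <- integer(length(lay$cls) - 1L)
  ci <- 0L
  for (j in seq_along(gaps)) {
    if (lay$cls[j] %in% CORE_CLASSES && lay$cls[j + 1L] %in% CORE_CLASSES) {
      ci <- ci + 1L
      gaps[j] <- gaps_core[ci]
    } else {
      gaps[j] <- flank_gap
    }
  }
  total <- sum(widths) + sum(gaps)
  if (total > n) {
    stop("arrangement of total width ", total,
         " does not fit in sequence of length ", n)
  }
  offset <- sample.int(n - total + 1L, 1L) - 1L

  starts <- integer(length(lay$cls))
  pos <- offset
  for (j in seq_along(lay$cls)) {
    starts[j] <- pos
    pos <- pos + widths[j] + if (j < length(lay$cls)) gaps[j] else 0L
  }

  chars <- seq_chars(seq)
  rows <- vector("list", length(lay$cls))
  for (j in seq_along(lay$cls)) {
    m <- pick_motif(motifs, lay$cls[j])
    word <- sample_site_sequence(m, cfg$plant_score_floor, params)
    plus_word <- if (lay$strand[j] == "+") word else revcomp_dna(word)
    chars[(starts[j] + 1L):(starts[j] + widths[j])] <-
      seq_chars(plus_word)
    rows[[j]] <- make_sites(seq_id, starts[j], starts[j] + widths[j],
                            lay$strand[j], m$tf_class, m$motif_id, 1.0,
                            plus_word)
  }
  planted <- sort_sites(do.call(rbind, rows))

  decoys <- empty_sites()
  if (cfg$decoy_density > 0) {
    res <- plant_decoys(chars, planted, cfg, motifs, seq_id)
    chars <- res$chars
    decoys <- res$decoys
  }

  truth <- truth_record(seq_id, planted, decoys, arrangement, grammar)
  scrub_background(paste(chars, collapse = ""), truth, motifs, params,
                   grammar)
}

truth_record <- function(seq_id, planted, decoys, arrangement, grammar) {
  # The intended tier is re-derived exactly the way the pipeline derives a
  # CRM tier: best candidate instance over the planted sites.
  ss <- structure(list(seq_id = seq_id, sites = sort_sites(planted)),
                  class = "site_set")
  best <- best_instance(enumerate_candidates(ss, grammar))
  if (is.null(best)) {
    flags <- evaluate_rules(empty_sites(), grammar)
    tier <- "INCOMPLETE"
  } else {
    flags <- best$flags
    tier <- best$tier
  }
  expected <- ARRANGEMENT_TIER[[arrangement]]
  if (tier != expected) {
    stop("generation-time self-check failed for '", seq_id, "': planted ",
         arrangement, " geometry classifies as ", tier, ", expected ",
         expected)
  }
  structure(list(seq_id = seq_id, sites = planted, decoys = decoys,
                 arrangement = arrangement, tier = tier,
                 flags = flags),
            class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("<truth_record> %s: %s -> %s; %d planted site(s), %d decoy(s)\n",
              x$seq_id, x$arrangement, x$tier, nrow(x$sites),
              nrow(x$decoys)))
  invisible(x)
}

# Plant decoy consensus sites (Ets / Su(H) / Su(H)-like words on a random
# strand) at random positions that do not overlap existing plants.
plant_decoys <- function(chars, planted, cfg, motifs, seq_id) {
  n <- length(chars)
  lambda <- cfg$decoy_density * n / 1000
  n_decoys <- stats::rpois(1L, lambda)
  cons <- Filter(function(m) m$model_kind == "CONSENSUS", motifs)
  occupied <- rep(FALSE, n)
  mark <- function(s, e) occupied[(s + 1L):e] <<- TRUE
  for (i in seq_len(nrow(planted))) mark(planted$start[i], planted$end[i])
  rows <- list()
  for (d in seq_len(n_decoys)) {
    m <- cons[[sample.int(length(cons), 1L)]]
    L <- motif_length(m)
    placed <- FALSE
    for (try in 1:50) {
      s <- sample.int(n - L + 1L, 1L) - 1L
      if (any(occupied[(s + 1L):(s + L)])) next
      strand <- sample(c("+", "-"), 1L)
      word <- sample_site_sequence(m)
      plus_word <- if (strand == "+") word else revcomp_dna(word)
      chars[(s + 1L):(s + L)] <- seq_chars(plus_word)
      mark(s, s + L)
      rows <- c(rows, list(make_sites(seq_id, s, s + L, strand, m$tf_class,
                                      m$motif_id, 1.0, plus_word)))
      placed <- TRUE
      break
    }
    if (!placed) next  # crowded sequence; drop this decoy
  }
  list(chars = chars,
       decoys = sort_sites(do.call(rbind, rows) %||% empty_sites()))
}

# Resample background positions until the only detectable sites are the
# planted ones (and decoys). A detection is "intended" when its
# (class, start, end) exactly matches a planted site, or when it overlaps a
# decoy of the same class by >= 0.5 reciprocally. Offending windows have
# their non-planted positions redrawn; a match lying wholly inside plants
# forces a redraw of the overlapped plant's realisation.
scrub_background <- function(seq, truth, motifs, params, grammar,
                             max_iter = 60L) {
  chars <- seq_chars(seq)
  n <- length(chars)
  gc <- mean(chars %in% c("G", "C"))
  if (gc <= 0 || gc >= 1) gc <- 0.5
  allowed <- rbind(truth$sites, truth$decoys)
  planted_mask <- rep(FALSE, n)
  for (i in seq_len(nrow(truth$sites))) {
    planted_mask[(truth$sites$start[i] + 1L):truth$sites$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(truth$decoys))) {
    planted_mask[(truth$decoys$start[i] + 1L):truth$decoys$end[i]] <- TRUE
  }
  intended <- function(det) {
    vapply(seq_len(nrow(det)), function(i) {
      exact <- any(truth$sites$tf_class == det$tf_class[i] &
                     truth$sites$start == det$start[i] &
                     truth$sites$end == det$end[i])
      if (exact) return(TRUE)
      if (nrow(truth$decoys)) {
        any(vapply(seq_len(nrow(truth$decoys)), function(k) {
          truth$decoys$tf_class[k] == det$tf_class[i] &&
            reciprocal_overlap(det$start[i], det$end[i],
                               truth$decoys$start[k],
                               truth$decoys$end[k]) >= 0.5
        }, logical(1)))
      } else {
        FALSE
      }
    }, logical(1))
  }
  for (iter in seq_len(max_iter)) {
    det <- detect_sites("scrub", paste(chars, collapse = ""), motifs,
                        params)$sites
    spurious <- if (nrow(det)) det[!intended(det), , drop = FALSE] else det
    if (!nrow(spurious)) {
      return(list(sequence = paste(chars, collapse = ""), truth = truth))
    }
    for (i in seq_len(nrow(spurious))) {
      span <- (spurious$start[i] + 1L):spurious$end[i]
      free <- span[!planted_mask[span]]
      if (length(free)) {
        chars[free] <- sample(DNA_BASES, length(free), replace = TRUE,
                              prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                       (1 - gc) / 2))
      } else {
        # Match wholly inside plants: redraw the realisation of each
        # overlapped planted site.
        for (k in seq_len(nrow(truth$sites))) {
          ts <- truth$sites[k, ]
          if (ts$start < spurious$end[i] && spurious$start[i] < ts$end) {
            m <- NULL
            for (mm in motifs) {
              if (mm$motif_id == ts$motif_id) m <- mm
            }
            word <- sample_site_sequence(m, 0.9, params)
            plus_word <- if (ts$strand == "+") word else revcomp_dna(word)
            chars[(ts$start + 1L):ts$end] <- seq_chars(plus_word)
            truth$sites$matched_seq[k] <- plus_word
          }
        }
      }
    }
  }
  stop("could not scrub spurious motif matches from '", truth$seq_id,
       "' after ", max_iter, " iterations")
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Generate a synthetic benchmark dataset
#'
#' Produces `cfg$n_sequences` background sequences with planted
#' arrangements (the arrangement vector is recycled across sequences) and
#' full truth labels. Deterministic for a given seed: each sequence uses a
#' substream mixed from the global seed and its index, so the dataset is
#' reproducible and order-independent.
#'
#' @param cfg a [simulation_config()] object.
#' @param grammar a [syntax_grammar()] object.
#' @param motifs motif set (see [synthetic_motif_set()]).
#' @param params a [scoring_params()] object.
#' @param dir optional output directory; when given, writes
#'   `sequences.fasta`, `truth.json` and `truth.bed`.
#' @return list with `sequences` (named character vector), `truth` (list of
#'   `truth_record`), `config`, and (when written) `files`.
#' @export
generate_dataset <- function(cfg, grammar = syntax_grammar(),
                             motifs = synthetic_motif_set(),
                             params = scoring_params(), dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  seqs <- character(cfg$n_sequences)
  truth <- vector("list", cfg$n_sequences)
  ids <- sprintf("synth_%03d", seq_len(cfg$n_sequences))
  for (i in seq_len(cfg$n_sequences)) {
    set.seed(mix_seed(cfg$seed, i))
    arr <- cfg$arrangement[((i - 1L) %% length(cfg$arrangement)) + 1L]
    bg <- draw_background(cfg$length, cfg$gc_content)
    res <- plant_arrangement(bg, arr, cfg, grammar, motifs, params,
                             seq_id = ids[i])
    seqs[i] <- res$sequence
    truth[[i]] <- res$truth
  }
  names(seqs) <- ids
  names(truth) <- ids
  out <- list(sequences = seqs, truth = truth, config = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "sequences.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(lapply(truth, function(t) {
      list(seq_id = t$seq_id, arrangement = t$arrangement, tier = t$tier,
           flags = as.list(t$flags), sites = t$sites, decoys = t$decoys)
    }), tj, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    pretty = TRUE)
    tb <- file.path(dir, "truth.bed")
    all_sites <- do.call(rbind, lapply(truth, function(t) t$sites))
    if (!is.null(all_sites) && nrow(all_sites)) {
      gr <- GenomicRanges::GRanges(
        seqnames = all_sites$seq_id,
        ranges = IRanges::IRanges(start = all_sites$start + 1L,
                                  end = all_sites$end),
        strand = all_sites$strand,
        name = paste(all_sites$tf_class, all_sites$motif_id, sep = ":"),
        score = as.integer(round(all_sites$score * 1000)))
      rtracklayer::export(gr, tb, format = "BED")
    } else {
      file.create(tb)
    }
    out$files <- c(fasta = fa, truth_json = tj, truth_bed = tb)
  }
  out
}

#' Score recovery of planted sites and tiers
#'
#' A call matches a truth site when it has the same class and reciprocal
#' overlap at least `overlap_fraction` (default 0.5; a one-bp-shifted call
#' on an 8-bp motif still matches). Precision counts matched calls over all
#' calls, recall matched truth sites over all truth sites; both are 1 when
#' the respective denominator is empty. The tier confusion matrix crosses
#' intended tiers (rows) with reported tiers (columns).
#'
#' @param truth list of `truth_record` objects (see [generate_dataset()]).
#' @param report an `sfze_scan` object over the same sequences.
#' @param overlap_fraction reciprocal-overlap threshold (default 0.5).
#' @return an object of class `recovery_metrics`: list with `precision`,
#'   `recall`, `tier_accuracy`, `confusion`, `n_truth_sites`, `n_calls`.
#' @export
evaluate_recovery <- function(truth, report, overlap_fraction = 0.5) {
  stopifnot(inherits(report, "sfze_scan"))
  missing <- setdiff(names(truth), names(report$results))
  if (length(missing)) {
    stop("report lacks sequence(s): ", paste(missing, collapse = ", "))
  }
  n_truth <- 0L
  n_calls <- 0L
  tp_truth <- 0L
  tp_calls <- 0L
  true_tiers <- character(length(truth))
  rep_tiers <- character(length(truth))
  for (i in seq_along(truth)) {
    t <- truth[[i]]
    r <- report$results[[t$seq_id]]
    calls <- r$sites$sites
    ts <- t$sites
    n_truth <- n_truth + nrow(ts)
    n_calls <- n_calls + nrow(calls)
    matched_call <- rep(FALSE, nrow(calls))
    for (k in seq_len(nrow(ts))) {
      hit <- which(calls$tf_class == ts$tf_class[k] &
                     vapply(seq_len(nrow(calls)), function(j) {
                       reciprocal_overlap(calls$start[j], calls$end[j],
                                          ts$start[k], ts$end[k]) >=
                         overlap_fraction
                     }, logical(1)))
      if (length(hit)) {
        tp_truth <- tp_truth + 1L
        matched_call[hit] <- TRUE
      }
    }
    tp_calls <- tp_calls + sum(matched_call)
    true_tiers[i] <- t$tier
    rep_tiers[i] <- r$tier
  }
  confusion <- table(intended = factor(true_tiers, levels = TIERS),
                     reported = factor(rep_tiers, levels = TIERS))
  structure(list(
    precision = if (n_calls) tp_calls / n_calls else 1,
    recall = if (n_truth) tp_truth / n_truth else 1,
    tier_accuracy = mean(true_tiers == rep_tiers),
    confusion = confusion,
    n_truth_sites = n_truth, n_calls = n_calls),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(paste0("<recovery_metrics> precision %.3f  recall %.3f  ",
                     "tier accuracy %.3f  (%d truth sites, %d calls)\n"),
              x$precision, x$recall, x$tier_accuracy, x$n_truth_sites,
              x$n_calls))
  print(x$confusion)
  invisible(x)
}
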