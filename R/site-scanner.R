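# Both-strand scanning of DNA sequences for consensus and matrix motifs,
# and aggregation into deduplicated per-sequence site sets.
#
# Coordinates are 0-based half-open on the plus strand throughout; a
# minus-strand site's matched_seq is still the plus-strand substring, whose
# reverse complement satisfies the motif.

empty_sites <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), tf_class = character(),
             motif_id = character(), score = numeric(),
             matched_seq = character(), stringsAsFactors = FALSE)
}

make_sites <- function(seq_id, start, end, strand, tf_class, motif_id,
                       score, matched_seq) {
  if (!length(start)) return(empty_sites())
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = strand, tf_class = tf_class,
             motif_id = motif_id, score = score, matched_seq = matched_seq,
             stringsAsFactors = FALSE)
}

# 1-based start positions of windows of chars matching a consensus code
# vector; windows containing any base outside the code's set (including
# non-ACGT letters) do not match.
consensus_hits <- function(chars, codes) {
  L <- length(codes)
  n <- length(chars)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  ok <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    ok <- ok & (chars[j:(nw + j - 1L)] %in% IUPAC_SETS[[codes[j]]])
  }
  which(ok)
}

#' Scan a sequence for a degenerate consensus motif
#'
#' Reports every window whose bases each fall in the corresponding IUPAC
#' set (exact matching, no mismatch allowance). Windows containing non-ACGT
#' bases are skipped. Minus-strand matches are found via the
#' reverse-complement consensus and reported with strand `-` on plus-strand
#' coordinates.
#'
#' @param seq DNA string.
#' @param m CONSENSUS-kind `motif_model`.
#' @param both_strands scan the minus strand as well (default `TRUE`).
#' @param seq_id identifier recorded on the sites.
#' @return data.frame of sites (0-based half-open `start`/`end`, `strand`,
#'   `tf_class`, `motif_id`, `score` = 1, plus-strand `matched_seq`).
#' @examples
#' scan_consensus("TAGGATT", motif_model("ETS_core", "E", consensus = "MGGAW"))
#' @export
scan_consensus <- function(seq, m, both_strands = TRUE, seq_id = "seq") {
  stopifnot(inherits(m, "motif_model"))
  if (m$model_kind != "CONSENSUS") {
    stop("motif '", m$motif_id, "' is not consensus-kind")
  }
  if (!nzchar(seq)) return(empty_sites())
  chars <- seq_chars(seq)
  L <- nchar(m$consensus)
  hit_df <- function(pos, strand) {
    make_sites(seq_id, pos - 1L, pos - 1L + L, strand, m$tf_class,
               m$motif_id, 1.0,
               vapply(pos, function(p) {
                 paste(chars[p:(p + L - 1L)], collapse = "")
               }, character(1)))
  }
  out <- hit_df(consensus_hits(chars, seq_chars(m$consensus)), "+")
  if (both_strands) {
    rc <- reverse_complement_consensus(m$consensus)
    out <- rbind(out, hit_df(consensus_hits(chars, seq_chars(rc)), "-"))
  }
  sort_sites(out)
}

# Additive window scores for an L-column weight matrix over an integer-coded
# sequence (A=1..T=4, NA for other letters). NA propagates, so windows with
# non-ACGT bases drop out.
window_scores <- function(idx, w) {
  L <- ncol(w)
  n <- length(idx)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + w[, j][idx[j:(nw + j - 1L)]]
  }
  sc
}

# Weight matrix for scoring reverse-complement windows on the plus strand.
revcomp_wm <- function(w) {
  w[4:1, ncol(w):1, drop = FALSE]
}

#' Scan a sequence with a position weight matrix
#'
#' Builds the log-odds weight matrix from the motif's count matrix and
#' reports every window whose relative score
#' \eqn{(s - s_{min})/(s_{max} - s_{min})} is at least the class threshold
#' in `params`. Windows containing non-ACGT bases are skipped.
#'
#' @param seq DNA string.
#' @param m MATRIX-kind `motif_model`.
#' @param params a [scoring_params()] object (thresholds, pseudocount,
#'   background).
#' @param both_strands scan the minus strand as well (default `TRUE`).
#' @param seq_id identifier recorded on the sites.
#' @return data.frame of sites; `score` is the relative score in
#'   \eqn{[0,1]}.
#' @export
scan_matrix <- function(seq, m, params = scoring_params(),
                        both_strands = TRUE, seq_id = "seq") {
  stopifnot(inherits(m, "motif_model"))
  if (m$model_kind != "MATRIX") {
    stop("motif '", m$motif_id, "' is not matrix-kind")
  }
  wm <- build_weight_matrix(m, params)
  if (wm$max_score - wm$min_score <= 0) {
    stop("motif '", m$motif_id, "': degenerate matrix (max_score == min_score)")
  }
  if (!nzchar(seq)) return(empty_sites())
  chars <- seq_chars(seq)
  idx <- match(chars, DNA_BASES)
  L <- ncol(wm$mat)
  thr <- params$rel_threshold[[m$tf_class]]
  hit_df <- function(w, strand) {
    sc <- window_scores(idx, w)
    rel <- (sc - wm$min_score) / (wm$max_score - wm$min_score)
    pos <- which(!is.na(rel) & rel >= thr)
    make_sites(seq_id, pos - 1L, pos - 1L + L, strand, m$tf_class,
               m$motif_id, rel[pos],
               vapply(pos, function(p) {
                 paste(chars[p:(p + L - 1L)], collapse = "")
               }, character(1)))
  }
  out <- hit_df(wm$mat, "+")
  if (both_strands) out <- rbind(out, hit_df(revcomp_wm(wm$mat), "-"))
  sort_sites(out)
}

#' Relative log-odds score of one window
#'
#' @param window DNA string of exactly the matrix length, A/C/G/T only.
#' @param wm a `weight_matrix` (see [build_weight_matrix()]).
#' @return relative score \eqn{(s - s_{min})/(s_{max} - s_{min})} in
#'   \eqn{[0,1]}; 1 for the per-position argmax word, 0 for the argmin word.
#' @export
relative_score <- function(window, wm) {
  stopifnot(inherits(wm, "weight_matrix"))
  idx <- match(seq_chars(window), DNA_BASES)
  if (length(idx) != ncol(wm$mat)) {
    stop("window length ", length(idx), " does not match matrix length ",
         ncol(wm$mat))
  }
  if (anyNA(idx)) stop("window contains non-ACGT bases")
  s <- sum(wm$mat[cbind(idx, seq_along(idx))])
  (s - wm$min_score) / (wm$max_score - wm$min_score)
}

sort_sites <- function(sites) {
  if (!nrow(sites)) return(sites)
  ord <- order(sites$start, sites$end, match(sites$strand, c("+", "-")),
               match(sites$tf_class, TF_CLASSES), sites$motif_id)
  out <- sites[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

overlap_frac <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  ov / min(e1 - s1, e2 - s2)
}

#' Detect all binding sites in one sequence
#'
#' Runs every motif over the sequence on both strands and merges the calls.
#' Within each SFZE class, among sites overlapping by more than
#' `overlap_fraction` (of the shorter site), only the best-scoring call is
#' retained (ties: smaller start, then plus strand). Sites of different
#' classes may overlap freely.
#'
#' @param seq_id sequence identifier.
#' @param seq DNA string.
#' @param motifs non-empty list of `motif_model` objects with unique ids.
#' @param params a [scoring_params()] object.
#' @param overlap_fraction same-class overlap tolerance (default 0.5).
#' @return an object of class `site_set`: list with `seq_id` and a sorted
#'   `sites` data.frame.
#' @export
detect_sites <- function(seq_id, seq, motifs, params = scoring_params(),
                         overlap_fraction = 0.5) {
  if (!length(motifs)) stop("empty motif list")
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate motif_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  calls <- lapply(motifs, function(m) {
    if (m$model_kind == "CONSENSUS") {
      scan_consensus(seq, m, both_strands = TRUE, seq_id = seq_id)
    } else {
      scan_matrix(seq, m, params, both_strands = TRUE, seq_id = seq_id)
    }
  })
  sites <- do.call(rbind, calls)
  sites <- dedup_sites(sites, overlap_fraction)
  structure(list(seq_id = seq_id, sites = sort_sites(sites)),
            class = "site_set")
}

# Greedy per-class dedup: best score first (ties -> smaller start, then plus
# strand); a site is kept only if it overlaps every kept same-class site by
# at most the allowed fraction.
dedup_sites <- function(sites, overlap_fraction) {
  if (!nrow(sites)) return(sites)
  keep <- logical(nrow(sites))
  for (cls in unique(sites$tf_class)) {
    rows <- which(sites$tf_class == cls)
    ord <- rows[order(-sites$score[rows], sites$start[rows],
                      match(sites$strand[rows], c("+", "-")),
                      sites$end[rows])]
    kept <- integer(0)
    for (r in ord) {
      clash <- any(vapply(kept, function(k) {
        overlap_frac(sites$start[r], sites$end[r],
                     sites$start[k], sites$end[k]) > overlap_fraction
      }, logical(1)))
      if (!clash) {
        kept <- c(kept, r)
        keep[r] <- TRUE
      }
    }
  }
  sites[keep, , drop = FALSE]
}

#' @export
print.site_set <- function(x, ...) {
  counts <- table(factor(x$sites$tf_class, levels = TF_CLASSES))
  cat(sprintf("<site_set> %s: %d sites (%s)\n", x$seq_id, nrow(x$sites),
              paste(sprintf("%s=%d", names(counts), counts),
                    collapse = " ")))
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}
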