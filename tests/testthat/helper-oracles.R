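# Independent brute-force oracles for the scanning and grammar engines.
# Deliberately naive and self-contained: they share no code with the
# package internals they are used to check.

ORACLE_BASES <- c("A", "C", "G", "T")

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_consensus_match <- function(word, consensus) {
  w <- strsplit(word, "")[[1]]
  cc <- strsplit(consensus, "")[[1]]
  length(w) == length(cc) &&
    all(mapply(function(b, code) b %in% ORACLE_IUPAC[[code]], w, cc))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(ORACLE_BASES), k),
                              stringsAsFactors = FALSE))
}

# Direct per-cell log-odds score of one window against a count matrix.
oracle_logodds <- function(word, counts, pseudocount, background) {
  w <- strsplit(word, "")[[1]]
  s <- 0
  for (i in seq_along(w)) {
    b <- match(w[i], ORACLE_BASES)
    num <- counts[b, i] + pseudocount * background[b]
    den <- sum(counts[, i]) + pseudocount
    s <- s + log2((num / den) / background[b])
  }
  s
}

# Exhaustive best/worst score over all |A|^L words (L small).
oracle_score_range <- function(counts, pseudocount, background) {
  words <- all_kmers(ncol(counts))
  sc <- vapply(words, oracle_logodds, numeric(1), counts = counts,
               pseudocount = pseudocount, background = background)
  c(min = min(sc), max = max(sc))
}

# Brute-force both-strand matrix scan: every window scored directly; hits
# where the relative score reaches the threshold, minus-strand windows
# scored on their reverse complement.
oracle_scan_matrix <- function(seq, counts, pseudocount, background,
                               threshold) {
  rng <- oracle_score_range(counts, pseudocount, background)
  L <- ncol(counts)
  chars <- strsplit(seq, "")[[1]]
  out <- list()
  for (p in seq_len(nchar(seq) - L + 1)) {
    word <- paste(chars[p:(p + L - 1)], collapse = "")
    if (grepl("[^ACGT]", word)) next
    for (st in c("+", "-")) {
      w <- if (st == "+") word else oracle_revcomp(word)
      rel <- (oracle_logodds(w, counts, pseudocount, background) -
                rng["min"]) / (rng["max"] - rng["min"])
      if (rel >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          start = p - 1L, end = p - 1L + L, strand = st, rel = unname(rel),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), rel = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end, match(df$strand, c("+", "-"))), ,
     drop = FALSE]
}

# Exhaustive subset oracle for candidate enumeration: every subset of the
# site rows whose class composition is one Zic, one Ets and 1..max_f Foxh1
# when those classes exist in the set (none otherwise), plus at most one
# Su(H)/Su(H)-like site.
oracle_candidate_subsets <- function(sites, max_f) {
  n <- nrow(sites)
  has <- function(cls) any(sites$tf_class %in% cls)
  subsets <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (!length(idx)) next
    cls <- sites$tf_class[idx]
    nf <- sum(cls == "F")
    nz <- sum(cls == "Z")
    ne <- sum(cls == "E")
    ns <- sum(cls %in% c("S", "S_LIKE"))
    ok <- (if (has("F")) nf >= 1 && nf <= max_f else nf == 0) &&
      (if (has("Z")) nz == 1 else nz == 0) &&
      (if (has("E")) ne == 1 else ne == 0) &&
      ns <= 1 &&
      !any(cls == "PROMOTER_ELEMENT")
    if (ok) subsets[[length(subsets) + 1]] <- sort(idx)
  }
  subsets
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(ORACLE_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Hand-built site data.frame for grammar tests.
site_row <- function(start, end, strand, tf_class, seq_id = "r",
                     motif_id = NULL, score = 1) {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = strand, tf_class = tf_class,
             motif_id = motif_id %||% paste0("m_", tf_class),
             score = score,
             matched_seq = strrep("N", end - start),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_site_set <- function(sites, seq_id = "r") {
  sites <- sites[order(sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(seq_id = seq_id, sites = sites), class = "site_set")
}

toy_matrix_motif <- function(id = "TOY", tf_class = "Z", L = 4,
                             counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(1, 4, L)
    for (j in seq_len(L)) counts[((j - 1) %% 4) + 1, j] <- 9
  }
  motif_model(id, tf_class, matrix = counts)
}
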