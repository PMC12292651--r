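# Internal constants and small sequence helpers shared across modules.

TF_CLASSES <- c("S", "S_LIKE", "F", "Z", "E", "PROMOTER_ELEMENT")
CORE_CLASSES <- c("F", "Z", "E")

# Tiers in decreasing rank order (used by best_instance()).
TIERS <- c("SFZE_FULL", "SFZE_LIKE_INVERTED", "SFZE_LIKE_SPAN",
           "SFZE_LIKE_ORIENT", "INCOMPLETE")

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("sequence must be a single character string")
  }
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' Reverse complement of a DNA or IUPAC string
#'
#' Works on any string over the 15-letter IUPAC nucleotide alphabet; plain
#' A/C/G/T sequences are a special case.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @examples
#' revcomp_dna("ACGT")
#' revcomp_dna("MGGAW")
#' @export
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    ch <- seq_chars(s)
    bad <- setdiff(unique(ch), names(IUPAC_COMPLEMENT))
    if (length(bad)) {
      stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
    }
    paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Positive rolling hash of a serialized object; provenance fingerprint only.
config_fingerprint <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  bytes <- utf8ToInt(s)
  p <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% p
  sprintf("%d", h)
}

# Deterministic per-sequence substream seed derived from a global seed.
mix_seed <- function(seed, i) {
  p <- 2147483647
  as.integer((((seed %% p) * 48271) %% p + i * 104729) %% p)
}
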