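# Binding-site models: position frequency matrices (PFMs) parsed from the
# JASPAR text format, degenerate IUPAC core consensi, and the log-odds
# scoring machinery built from them.

#' Construct a binding-site model
#'
#' A motif model is either a position frequency matrix (4 x L nonnegative
#' counts, rows A, C, G, T) or a degenerate IUPAC consensus string, tagged
#' with the SFZE class of the factor it represents: `"S"` (Su(H)),
#' `"S_LIKE"` (suboptimal Su(H)-like), `"F"` (Foxh1), `"Z"` (Zic),
#' `"E"` (Ets) or `"PROMOTER_ELEMENT"`.
#'
#' @param motif_id unique identifier.
#' @param tf_class one of `"S"`, `"S_LIKE"`, `"F"`, `"Z"`, `"E"`,
#'   `"PROMOTER_ELEMENT"`.
#' @param matrix 4 x L numeric count matrix (rows A, C, G, T), or `NULL`.
#' @param consensus IUPAC consensus string, or `NULL`. Exactly one of
#'   `matrix`/`consensus` must be given.
#' @param source free-text provenance tag.
#' @return an object of class `motif_model`.
#' @examples
#' motif_model("ETS_core", "E", consensus = "MGGAW")
#' @export
motif_model <- function(motif_id, tf_class, matrix = NULL, consensus = NULL,
                        source = "") {
  stopifnot(is.character(motif_id), length(motif_id) == 1L, nzchar(motif_id))
  tf_class <- match.arg(tf_class, TF_CLASSES)
  if (is.null(matrix) == is.null(consensus)) {
    stop("motif '", motif_id,
         "': exactly one of matrix/consensus must be supplied")
  }
  if (!is.null(matrix)) {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) != 4L) {
      stop("motif '", motif_id, "': matrix must have 4 rows (A,C,G,T)")
    }
    if (!is.numeric(matrix) || anyNA(matrix) || any(matrix < 0)) {
      stop("motif '", motif_id, "': matrix counts must be nonnegative numbers")
    }
    if (ncol(matrix) < 4L) {
      stop("motif '", motif_id, "': motif length must be >= 4")
    }
    if (any(colSums(matrix) == 0)) {
      stop("motif '", motif_id, "': matrix has an all-zero column")
    }
    rownames(matrix) <- DNA_BASES
    kind <- "MATRIX"
  } else {
    consensus <- toupper(consensus)
    stopifnot(is.character(consensus), length(consensus) == 1L)
    ch <- seq_chars(consensus)
    if (length(ch) < 4L) {
      stop("motif '", motif_id, "': consensus length must be >= 4")
    }
    bad <- setdiff(unique(ch), names(IUPAC_SETS))
    if (length(bad)) {
      stop("motif '", motif_id, "': invalid IUPAC code(s): ",
           paste(bad, collapse = ", "))
    }
    kind <- "CONSENSUS"
  }
  structure(
    list(motif_id = motif_id, tf_class = tf_class, model_kind = kind,
         matrix = matrix, consensus = consensus, source = source),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s  class=%s  kind=%s  L=%d\n",
              x$motif_id, x$tf_class, x$model_kind, motif_length(x)))
  if (x$model_kind == "CONSENSUS") {
    cat("  consensus:", x$consensus, "\n")
  } else {
    print(x$matrix)
  }
  invisible(x)
}

#' Motif length in base pairs
#' @param m a `motif_model`.
#' @return integer length.
#' @export
motif_length <- function(m) {
  if (m$model_kind == "MATRIX") ncol(m$matrix) else nchar(m$consensus)
}

#' Parse motifs from JASPAR matrix text
#'
#' Reads the JASPAR position-frequency-matrix text format: a header line
#' starting with `>` followed by four base rows, with or without row labels
#' and brackets. Row order is normalized to A, C, G, T regardless of input
#' labelling.
#'
#' @param text a file path or the JASPAR text itself (anything containing a
#'   newline is treated as text).
#' @param tf_class SFZE class to tag parsed motifs with; either a single
#'   value applied to all records or a named vector `motif_id -> class`.
#' @param source provenance tag recorded on each model.
#' @return list of `motif_model` objects (MATRIX kind).
#' @examples
#' txt <- ">M1 toy\nA [10 0 0 2]\nC [0 10 0 2]\nG [0 0 10 2]\nT [0 0 0 4]\n"
#' parse_jaspar(txt, tf_class = "Z")
#' @export
parse_jaspar <- function(text, tf_class = "Z", source = "JASPAR") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  starts <- grep("^>", lines)
  if (!length(starts) || starts[1] != 1L) {
    stop("malformed JASPAR input: no '>' header at start")
  }
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[bounds[k]])
    toks <- strsplit(header, "\\s+")[[1]]
    if (!length(toks) || !nzchar(toks[1])) {
      stop("malformed JASPAR header in record ", k)
    }
    id <- toks[1]
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L) {
      stop("record '", id, "': expected 4 base rows, found ", length(body))
    }
    labels <- character(4)
    rows <- vector("list", 4)
    for (j in 1:4) {
      ln <- gsub("\\[|\\]", " ", body[j])
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      if (toupper(tk[1]) %in% DNA_BASES && is.na(suppressWarnings(
        as.numeric(tk[1])))) {
        labels[j] <- toupper(tk[1])
        tk <- tk[-1]
      }
      vals <- suppressWarnings(as.numeric(tk))
      if (anyNA(vals) || !length(vals)) {
        stop("record '", id, "': non-numeric counts in row ", j)
      }
      if (any(vals < 0)) {
        stop("record '", id, "': negative counts in row ", j)
      }
      rows[[j]] <- vals
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("record '", id, "': unequal row lengths (",
           paste(lens, collapse = ","), ")")
    }
    mat <- do.call(rbind, rows)
    if (all(nzchar(labels))) {
      if (!setequal(labels, DNA_BASES)) {
        stop("record '", id, "': row labels must be a permutation of A,C,G,T")
      }
      mat <- mat[match(DNA_BASES, labels), , drop = FALSE]
    }
    cls <- if (length(tf_class) > 1L || !is.null(names(tf_class))) {
      unname(tf_class[id]) %||% stop("no tf_class given for motif '", id, "'")
    } else {
      tf_class
    }
    if (is.na(cls)) stop("no tf_class given for motif '", id, "'")
    out[[k]] <- motif_model(id, cls, matrix = mat, source = source)
  }
  out
}

#' Serialize matrix motifs to JASPAR text
#'
#' @param motifs a `motif_model` or list of them (MATRIX kind).
#' @param path optional output file; if `NULL` the text is returned.
#' @return the JASPAR text, invisibly when written to `path`.
#' @export
write_jaspar <- function(motifs, path = NULL) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  txt <- vapply(motifs, function(m) {
    if (m$model_kind != "MATRIX") {
      stop("motif '", m$motif_id, "' is not matrix-kind")
    }
    rows <- vapply(1:4, function(j) {
      sprintf("%s  [ %s ]", DNA_BASES[j],
              paste(format(m$matrix[j, ], trim = TRUE), collapse = " "))
    }, character(1))
    paste(c(paste0(">", m$motif_id, " ", m$motif_id), rows), collapse = "\n")
  }, character(1))
  txt <- paste0(paste(txt, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Scoring parameters for matrix motifs
#'
#' @param pseudocount positive pseudocount added per matrix column,
#'   distributed by the background composition. Default 0.8.
#' @param background length-4 base composition (A, C, G, T); positive,
#'   summing to 1. Default uniform, appropriate for cross-species scanning
#'   with no single genome composition.
#' @param rel_threshold named vector of minimum relative scores (in
#'   \eqn{[0,1]}) per SFZE class; classes not named fall back to `default`.
#' @param default fallback relative-score threshold (default 0.8).
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(pseudocount = 0.8,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           rel_threshold = NULL, default = 0.8) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount > 0)
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  names(background) <- DNA_BASES
  stopifnot(is.numeric(default), default >= 0, default <= 1)
  thr <- setNames(rep(default, length(TF_CLASSES)), TF_CLASSES)
  if (!is.null(rel_threshold)) {
    if (is.null(names(rel_threshold)) ||
        !all(names(rel_threshold) %in% TF_CLASSES)) {
      stop("rel_threshold must be named by tf_class")
    }
    if (any(rel_threshold < 0 | rel_threshold > 1)) {
      stop("rel_threshold values must lie in [0,1]")
    }
    thr[names(rel_threshold)] <- rel_threshold
  }
  structure(list(pseudocount = pseudocount, background = background,
                 rel_threshold = thr),
            class = "scoring_params")
}

#' Build a log-odds weight matrix from a count matrix
#'
#' Each cell is
#' \deqn{w_{b,i} = \log_2\frac{(n_{b,i} + p\,q_b)/(N_i + p)}{q_b}}
#' where \eqn{n_{b,i}} is the count of base \eqn{b} at position \eqn{i},
#' \eqn{N_i} the column sum, \eqn{p} the pseudocount and \eqn{q_b} the
#' background probability. `min_score`/`max_score` are the sums of the
#' per-position minima/maxima.
#'
#' @param m a MATRIX-kind `motif_model`.
#' @param params a [scoring_params()] object.
#' @return an object of class `weight_matrix`.
#' @export
build_weight_matrix <- function(m, params = scoring_params()) {
  stopifnot(inherits(m, "motif_model"))
  if (m$model_kind != "MATRIX") {
    stop("motif '", m$motif_id, "' is not matrix-kind")
  }
  cs <- colSums(m$matrix)
  if (any(cs == 0)) stop("motif '", m$motif_id, "': zero column sum")
  bg <- params$background
  pc <- params$pseudocount
  p <- sweep(sweep(m$matrix, 1, pc * bg, "+"), 2, cs + pc, "/")
  w <- log2(sweep(p, 1, bg, "/"))
  structure(
    list(motif_id = m$motif_id, tf_class = m$tf_class, mat = w,
         min_score = sum(apply(w, 2, min)),
         max_score = sum(apply(w, 2, max))),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %s  L=%d  score range [%.3f, %.3f]\n",
              x$motif_id, ncol(x$mat), x$min_score, x$max_score))
  invisible(x)
}

#' Base set of an IUPAC nucleotide code
#'
#' @param code a single IUPAC character.
#' @return character vector of matching bases, e.g. `iupac_set("M")` is
#'   `c("A", "C")`.
#' @export
iupac_set <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  s <- IUPAC_SETS[[toupper(code)]]
  if (is.null(s)) stop("invalid IUPAC code: '", code, "'")
  s
}

#' Reverse complement of an IUPAC consensus
#'
#' Reverses the string and complements each degenerate code
#' (M <-> K, R <-> Y, W <-> W, S <-> S, B <-> V, D <-> H, N <-> N), so that
#' matching the result on the plus strand is equivalent to matching the
#' original consensus on the minus strand. The operation is an involution.
#'
#' @param consensus IUPAC string.
#' @return the reverse-complemented IUPAC string.
#' @examples
#' reverse_complement_consensus("MGGAW")    # "WTCCK"
#' reverse_complement_consensus("GTGTRGAR") # "YTCYACAC"
#' @export
reverse_complement_consensus <- function(consensus) {
  revcomp_dna(consensus)
}

#' Built-in SFZE consensus motifs
#'
#' The Ets core `MGGAW`, the Su(H) core `GTGTRGAR`, and the suboptimal
#' Su(H)-like 7-mers `NTGRGAR` and `GTGRGAN`.
#'
#' @return list of CONSENSUS-kind `motif_model` objects.
#' @export
sfze_consensus_motifs <- function() {
  list(
    motif_model("ETS_core", "E", consensus = "MGGAW",
                source = "Ets core consensus"),
    motif_model("SUH_core", "S", consensus = "GTGTRGAR",
                source = "Su(H) core consensus"),
    motif_model("SUH_like_5p", "S_LIKE", consensus = "NTGRGAR",
                source = "suboptimal Su(H)-like consensus"),
    motif_model("SUH_like_3p", "S_LIKE", consensus = "GTGRGAN",
                source = "suboptimal Su(H)-like consensus")
  )
}

#' Assemble a full SFZE motif set
#'
#' Combines user-supplied Zic and Foxh1 matrices (JASPAR files or
#' `motif_model` objects) with the built-in Ets/Su(H)/Su(H)-like consensi.
#' Vertebrate Zic-family and FOXH1 JASPAR entries are the recommended
#' sources for the two matrices; they are deliberately configuration, not
#' hard-coded.
#'
#' @param zic,foxh1 path to a JASPAR file or a MATRIX-kind `motif_model`.
#' @return list of `motif_model` objects covering classes Z, F, E, S,
#'   S_LIKE.
#' @export
sfze_motif_set <- function(zic, foxh1) {
  as_models <- function(x, cls) {
    if (inherits(x, "motif_model")) return(list(x))
    if (is.list(x)) return(x)
    parse_jaspar(x, tf_class = cls)
  }
  c(as_models(zic, "Z"), as_models(foxh1, "F"), sfze_consensus_motifs())
}

#' Synthetic demonstration motif set
#'
#' Loads the small synthetic Zic-like and Foxh1-like matrices bundled with
#' the package (clearly labelled synthetic; they are test/simulation
#' stand-ins, not curated JASPAR entries) and combines them with the
#' built-in consensi.
#'
#' @return list of `motif_model` objects.
#' @export
synthetic_motif_set <- function() {
  path <- system.file("extdata", "synthetic_motifs.jaspar",
                      package = "sfzescan", mustWork = TRUE)
  sfze_motif_set(
    zic = parse_jaspar(path, tf_class = c(SYN_ZIC = "Z", SYN_FOXH1 = "F"),
                       source = "synthetic")[[1]],
    foxh1 = parse_jaspar(path, tf_class = c(SYN_ZIC = "Z", SYN_FOXH1 = "F"),
                         source = "synthetic")[[2]]
  )
}

#' Read a motif/scoring configuration block
#'
#' Reads a YAML or JSON file with optional keys `pseudocount`, `background`
#' (length-4, order A,C,G,T), `rel_threshold` (map class -> value) and
#' `motifs` (list of blocks with `id`, `tf_class`, plus either `jaspar`,
#' a file path, or `consensus`).
#'
#' @param path configuration file (`.yml`/`.yaml`/`.json`).
#' @return list with elements `params` ([scoring_params()]) and `motifs`
#'   (possibly empty list of `motif_model`).
#' @export
read_motif_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  params <- scoring_params(
    pseudocount = cfg$pseudocount %||% 0.8,
    background = cfg$background %||% rep(0.25, 4),
    rel_threshold = if (!is.null(cfg$rel_threshold)) {
      unlist(cfg$rel_threshold)
    }
  )
  motifs <- list()
  for (blk in cfg$motifs %||% list()) {
    if (!is.null(blk$consensus)) {
      motifs <- c(motifs, list(motif_model(blk$id, blk$tf_class,
                                           consensus = blk$consensus,
                                           source = "config")))
    } else if (!is.null(blk$jaspar)) {
      jp <- blk$jaspar
      if (!file.exists(jp)) {
        jp <- file.path(dirname(path), blk$jaspar)
      }
      motifs <- c(motifs, parse_jaspar(jp, tf_class = blk$tf_class))
    } else {
      stop("motif block '", blk$id %||% "?",
           "' needs either 'consensus' or 'jaspar'")
    }
  }
  list(params = params, motifs = motifs)
}
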