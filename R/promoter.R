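# Core-promoter and promoter-proximal element annotation around a stated
# transcription (or translation) start site.

#' Default promoter element definitions
#'
#' Standard literature consensi and positional windows, all relative to a
#' 0-based TSS index; every consensus and window is overridable. These are
#' conventional defaults, used to deduce promoters from sequence:
#' \itemize{
#'   \item TATA box `TATAWAWR`, element start within \eqn{[-40,-20]} of the
#'     TSS;
#'   \item initiator (Inr) `YYANWYY`, window spanning the TSS;
#'   \item downstream TFIIB recognition element (BREd) `RTDKKKK`,
#'     immediately 3' of a TATA call;
#'   \item downstream promoter element (DPE) `RGWYV`, start within
#'     \eqn{[+25,+35]};
#'   \item CCAAT box `CCAAT` and GC box `GGGCGG`, promoter-proximal,
#'     anywhere within \eqn{[-250,-1]}.
#' }
#'
#' @return list of element definitions (name, consensus, window rule).
#' @export
promoter_elements <- function() {
  list(
    list(name = "TATA", consensus = "TATAWAWR", rule = "start_window",
         window = c(-40L, -20L)),
    list(name = "Inr", consensus = "YYANWYY", rule = "spans_tss"),
    list(name = "BREd", consensus = "RTDKKKK", rule = "after_tata"),
    list(name = "DPE", consensus = "RGWYV", rule = "start_window",
         window = c(25L, 35L)),
    list(name = "CCAAT", consensus = "CCAAT", rule = "within_window",
         window = c(-250L, -1L)),
    list(name = "GC_box", consensus = "GGGCGG", rule = "within_window",
         window = c(-250L, -1L))
  )
}

#' Annotate core promoter elements around a TSS
#'
#' Scans the plus (coding) strand for each promoter element consensus and
#' flags calls falling inside the element's positional window relative to
#' the stated TSS. All consensus matches in the sequence are reported;
#' `in_window` marks the positionally compliant ones.
#'
#' @param seq promoter-region DNA string.
#' @param tss_index 0-based index of the TSS within `seq`.
#' @param elements element definitions (see [promoter_elements()]).
#' @return an object of class `promoter_annotation`: data.frame with
#'   columns `element`, `start`, `end` (0-based half-open), `strand`,
#'   `matched_seq`, `offset` (start minus TSS) and `in_window`.
#' @examples
#' s <- paste0(strrep("T", 20), "CCAAT", strrep("T", 95), "TATAAAAG",
#'             strrep("T", 20), "TCATTCC", strrep("T", 20))
#' annotate_promoter(s, tss_index = 151)
#' @export
annotate_promoter <- function(seq, tss_index, elements = promoter_elements()) {
  n <- nchar(seq)
  if (tss_index < 0 || tss_index >= n) {
    stop("tss_index ", tss_index, " outside sequence of length ", n)
  }
  chars <- seq_chars(seq)
  one <- function(el) {
    pos <- consensus_hits(chars, seq_chars(el$consensus))
    if (!length(pos)) return(NULL)
    L <- nchar(el$consensus)
    start <- pos - 1L
    end <- start + L
    offset <- start - tss_index
    data.frame(element = el$name, start = start, end = end, strand = "+",
               matched_seq = vapply(pos, function(p) {
                 paste(chars[p:(p + L - 1L)], collapse = "")
               }, character(1)),
               offset = offset, in_window = FALSE,
               stringsAsFactors = FALSE)
  }
  calls <- lapply(elements, one)
  names(calls) <- vapply(elements, function(e) e$name, character(1))
  for (el in elements) {
    df <- calls[[el$name]]
    if (is.null(df)) next
    df$in_window <- switch(
      el$rule,
      start_window = df$offset >= el$window[1] & df$offset <= el$window[2],
      spans_tss = df$start <= tss_index & df$end > tss_index,
      within_window = (df$start - tss_index) >= el$window[1] &
        (df$end - 1L - tss_index) <= el$window[2],
      after_tata = {
        tata <- calls[["TATA"]]
        tata_ends <- if (is.null(tata)) integer(0) else {
          tata$end[tata$in_window]
        }
        df$start %in% tata_ends
      },
      stop("unknown promoter element rule: ", el$rule)
    )
    calls[[el$name]] <- df
  }
  out <- do.call(rbind, calls) %||%
    data.frame(element = character(), start = integer(), end = integer(),
               strand = character(), matched_seq = character(),
               offset = integer(), in_window = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(out$start, out$element), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("promoter_annotation", "data.frame"),
            tss_index = tss_index)
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter_annotation> TSS at %d; %d call(s), %d in window\n",
              attr(x, "tss_index"), nrow(x), sum(x$in_window)))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
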