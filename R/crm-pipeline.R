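# End-to-end CRM scanning: input readers (FASTA / BED), the run_scan
# driver producing a classified report, core-promoter element annotation,
# and standard-format writers (GFF3, BED, TSV, JSON).

#' Construct a CRM record
#'
#' @param name unique CRM name.
#' @param seq_id source sequence (contig/scaffold) identifier.
#' @param start,end 0-based half-open genome coordinates (0..length for
#'   CRMs supplied directly as FASTA records).
#' @param sequence plus-strand DNA sequence of the region; its length must
#'   equal `end - start`.
#' @return an object of class `crm_record`.
#' @export
crm_record <- function(name, seq_id, start, end, sequence) {
  stopifnot(start >= 0, end > start)
  if (nchar(sequence) != end - start) {
    stop("CRM '", name, "': sequence length ", nchar(sequence),
         " != end - start = ", end - start)
  }
  structure(list(name = name, seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end), sequence = toupper(sequence)),
            class = "crm_record")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (genome or CRM multi-FASTA).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read intervals from a BED file
#'
#' Regions are scanned on the plus strand of the given genome (mirrored
#' arrangements are handled by the grammar), so a BED strand column is
#' ignored with a warning.
#'
#' @param path BED file.
#' @return data.frame with columns `seq_id`, `start` (0-based), `end`,
#'   `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands != "*")) {
    warning("BED strand column ignored; regions are scanned on the plus ",
            "strand and mirrored arrangements handled by the grammar")
  }
  nm <- GenomicRanges::mcols(gr)$name
  if (is.null(nm) || all(is.na(nm))) {
    nm <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  }
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = as.character(nm), stringsAsFactors = FALSE)
}

#' Extract CRM sequences from a genome
#'
#' @param genome named character vector of sequences (see [read_fasta()]),
#'   a `DNAStringSet`, or a FASTA path.
#' @param regions interval data.frame from [read_bed()].
#' @return list of [crm_record()] objects (plus-strand sequences).
#' @export
extract_crms <- function(genome, regions) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(toupper(as.character(genome)),
                       sub("\\s.*$", "", names(genome)))
  }
  if (!nrow(regions)) return(list())
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!r$seq_id %in% names(genome)) {
      stop("region '", r$name, "': sequence '", r$seq_id,
           "' not found in genome")
    }
    len <- nchar(genome[[r$seq_id]])
    if (r$start < 0 || r$end > len || r$start >= r$end) {
      stop("region '", r$name, "': interval [", r$start, ",", r$end,
           ") out of bounds for '", r$seq_id, "' (length ", len, ")")
    }
    out[[i]] <- crm_record(r$name, r$seq_id, r$start, r$end,
                           substr(genome[[r$seq_id]], r$start + 1L, r$end))
  }
  nms <- vapply(out, function(x) x$name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate CRM name: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  out
}

#' Turn a CRM multi-FASTA into CRM records
#'
#' @param x FASTA path or named character vector of CRM sequences.
#' @return list of [crm_record()] objects with coordinates 0..length.
#' @export
crms_from_fasta <- function(x) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fasta(x)
  } else {
    x
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("CRM sequences must be named")
  }
  lapply(names(seqs), function(nm) {
    crm_record(nm, nm, 0L, nchar(seqs[[nm]]), seqs[[nm]])
  })
}

#' Scan and classify a set of CRMs
#'
#' Runs site detection, grammar enumeration and tier classification on each
#' CRM. The run is fully deterministic given the inputs and configuration;
#' the configuration fingerprint and an optional seed are echoed into the
#' report for provenance.
#'
#' @param crms list of [crm_record()] objects (see [extract_crms()] /
#'   [crms_from_fasta()]).
#' @param motifs list of `motif_model` objects (see [sfze_motif_set()]).
#' @param grammar a [syntax_grammar()] object.
#' @param params a [scoring_params()] object.
#' @param overlap_fraction same-class overlap tolerance for site dedup.
#' @param seed optional seed echoed into the metadata (the scan itself uses
#'   no randomness).
#' @param verbose log one line per CRM (default `FALSE`).
#' @return an object of class `sfze_scan`: per CRM the `site_set`, all
#'   `syntax_instance`s, the best instance, the tier and the arrangement
#'   string, plus run metadata.
#' @export
run_scan <- function(crms, motifs, grammar = syntax_grammar(),
                     params = scoring_params(), overlap_fraction = 0.5,
                     seed = NA, verbose = FALSE) {
  if (inherits(crms, "crm_record")) crms <- list(crms)
  stopifnot(length(crms) >= 0, all(vapply(crms, inherits, logical(1),
                                          "crm_record")))
  results <- lapply(crms, function(crm) {
    tryCatch({
      ss <- detect_sites(crm$name, crm$sequence, motifs, params,
                         overlap_fraction)
      inst <- enumerate_candidates(ss, grammar)
      best <- best_instance(inst)
      tier <- if (is.null(best)) "INCOMPLETE" else best$tier
      if (verbose) {
        message(sprintf("[scan] %s: %d sites, %d candidates, tier %s",
                        crm$name, nrow(ss$sites), length(inst), tier))
      }
      list(sites = ss, instances = inst, best = best, tier = tier,
           arrangement = if (is.null(best)) "" else best$arrangement)
    }, error = function(e) {
      stop("CRM '", crm$name, "': ", conditionMessage(e), call. = FALSE)
    })
  })
  names(results) <- vapply(crms, function(x) x$name, character(1))
  cfg <- list(grammar = unclass(grammar),
              params = unclass(params),
              overlap_fraction = overlap_fraction)
  structure(list(crms = crms, results = results, grammar = grammar,
                 params = params,
                 meta = list(package_version =
                               as.character(utils::packageVersion("sfzescan")),
                             config_fingerprint = config_fingerprint(cfg),
                             overlap_fraction = overlap_fraction,
                             seed = seed)),
            class = "sfze_scan")
}

#' @export
print.sfze_scan <- function(x, ...) {
  cat(sprintf("<sfze_scan> %d CRM(s), config %s\n", length(x$crms),
              x$meta$config_fingerprint))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Per-CRM summary table of a scan
#'
#' @param object an `sfze_scan` object.
#' @param ... unused.
#' @return data.frame with one row per CRM: name, site counts per class,
#'   tier, core span of the best instance, and arrangement notation.
#' @export
summary.sfze_scan <- function(object, ...) {
  rows <- lapply(names(object$results), function(nm) {
    r <- object$results[[nm]]
    counts <- table(factor(r$sites$sites$tf_class, levels = TF_CLASSES))
    data.frame(name = nm,
               n_S = as.integer(counts[["S"]]),
               n_S_LIKE = as.integer(counts[["S_LIKE"]]),
               n_F = as.integer(counts[["F"]]),
               n_Z = as.integer(counts[["Z"]]),
               n_E = as.integer(counts[["E"]]),
               tier = r$tier,
               core_span = if (is.null(r$best)) NA_integer_ else
                 as.integer(r$best$core_span),
               arrangement = r$arrangement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(name = character(), n_S = integer(), n_S_LIKE = integer(),
               n_F = integer(), n_Z = integer(), n_E = integer(),
               tier = character(), core_span = integer(),
               arrangement = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# All detected sites of a report in genome coordinates.
report_sites <- function(report) {
  rows <- lapply(seq_along(report$crms), function(i) {
    crm <- report$crms[[i]]
    s <- report$results[[crm$name]]$sites$sites
    if (!nrow(s)) return(NULL)
    data.frame(crm = crm$name, seq_id = crm$seq_id,
               start = crm$start + s$start, end = crm$start + s$end,
               strand = s$strand, tf_class = s$tf_class,
               motif_id = s$motif_id, score = s$score,
               matched_seq = s$matched_seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(crm = character(), seq_id = character(), start = integer(),
               end = integer(), strand = character(), tf_class = character(),
               motif_id = character(), score = numeric(),
               matched_seq = character(), stringsAsFactors = FALSE)
}

#' Write detected sites as GFF3
#'
#' One `region` feature per CRM (with `tier` and `arrangement` attributes)
#' and one `TF_binding_site` feature per detected site (with `tf_class`,
#' `motif_id` and relative score). Coordinates are 1-based inclusive.
#'
#' @param report an `sfze_scan` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sites_gff3 <- function(report, path) {
  sites <- report_sites(report)
  crm_df <- data.frame(
    seq_id = vapply(report$crms, function(x) x$seq_id, character(1)),
    start = vapply(report$crms, function(x) x$start, integer(1)),
    end = vapply(report$crms, function(x) x$end, integer(1)),
    name = vapply(report$crms, function(x) x$name, character(1)),
    stringsAsFactors = FALSE)
  gr_regions <- GenomicRanges::GRanges(
    seqnames = crm_df$seq_id,
    ranges = IRanges::IRanges(start = crm_df$start + 1L, end = crm_df$end),
    strand = "*",
    source = "sfzescan", type = "region",
    Name = crm_df$name,
    tier = vapply(crm_df$name, function(nm) report$results[[nm]]$tier,
                  character(1)),
    arrangement = vapply(crm_df$name, function(nm) {
      report$results[[nm]]$arrangement
    }, character(1)),
    tf_class = NA_character_, motif_id = NA_character_,
    score = NA_real_)
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$seq_id,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand,
    source = "sfzescan", type = "TF_binding_site",
    Name = sites$crm, tier = NA_character_, arrangement = NA_character_,
    tf_class = sites$tf_class, motif_id = sites$motif_id,
    score = sites$score)
  rtracklayer::export(c(gr_regions, gr_sites), path, format = "gff3")
  invisible(path)
}

#' Write detected sites as BED
#'
#' 0-based BED6 with `name` = `class:motif_id` and the relative score
#' scaled to 0--1000 (score 1.0 maps to 1000).
#'
#' @param report an `sfze_scan` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sites_bed <- function(report, path) {
  sites <- report_sites(report)
  gr <- GenomicRanges::GRanges(
    seqnames = sites$seq_id,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand,
    name = paste(sites$tf_class, sites$motif_id, sep = ":"),
    score = as.integer(round(sites$score * 1000)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write the per-CRM summary as TSV
#'
#' @param report an `sfze_scan` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_summary_tsv <- function(report, path) {
  utils::write.table(summary(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

instance_to_list <- function(inst) {
  if (is.null(inst)) return(NULL)
  list(members = inst$member_sites, core_span = inst$core_span,
       arrangement = inst$arrangement, flags = as.list(inst$flags),
       tier = inst$tier)
}

report_to_list <- function(report) {
  list(
    package = "sfzescan",
    meta = report$meta,
    grammar = unclass(report$grammar),
    params = unclass(report$params),
    crms = lapply(report$crms, function(crm) {
      r <- report$results[[crm$name]]
      list(name = crm$name, seq_id = crm$seq_id, start = crm$start,
           end = crm$end, length = crm$end - crm$start,
           tier = r$tier, arrangement = r$arrangement,
           sites = r$sites$sites,
           instances = lapply(r$instances, instance_to_list),
           best = instance_to_list(r$best))
    })
  )
}

#' Write the full report as JSON
#'
#' Lossless serialization of sites, candidate instances, flags, tiers and
#' run metadata; [read_report_json()] reads it back.
#'
#' @param report an `sfze_scan` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report_json()]
#'
#' @param path JSON file.
#' @return the report as a nested list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
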