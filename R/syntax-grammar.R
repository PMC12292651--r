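# The SFZE grammar engine: enumerate candidate site combinations, evaluate
# the order / orientation / spacing rules, and classify each candidate into
# a compliance tier.
#
# The grammar encodes the arrangement seen in brachyury notochord enhancers:
# class order 5'-Su(H)-Foxh1(-Foxh1)-Zic-Ets-3' (or its mirror image),
# face-to-face orientation of the Zic and Ets sites, the Foxh1 site
# adjacent to Zic on the same strand, and a Foxh1-Zic-Ets core spanning at
# most ~one nucleosome length (147 bp). The Su(H) site's position is the
# least constrained.

#' Construct an SFZE grammar rule set
#'
#' @param max_f maximum number of Foxh1 slots in the order template
#'   (default 2; at least one Foxh1 is always required for a complete
#'   core).
#' @param allow_mirror accept the mirrored (reverse-reading) arrangement as
#'   order-compliant (default `TRUE`).
#' @param max_core_span maximum Foxh1-Zic-Ets core span in bp (default 147,
#'   one nucleosome length).
#' @param s_max_distance maximum distance (bp) from a Su(H)/Su(H)-like site
#'   to the core bounding interval for it to count as present; default
#'   `Inf`, i.e. anywhere within the scanned region.
#' @param enumeration_budget maximum number of candidate combinations per
#'   region before [enumerate_candidates()] errors (default 10000).
#' @return an object of class `syntax_grammar`.
#' @export
syntax_grammar <- function(max_f = 2L, allow_mirror = TRUE,
                           max_core_span = 147L, s_max_distance = Inf,
                           enumeration_budget = 10000L) {
  stopifnot(max_f >= 1L, max_core_span > 0, s_max_distance >= 0,
            enumeration_budget >= 1L)
  structure(list(max_f = as.integer(max_f),
                 allow_mirror = isTRUE(allow_mirror),
                 max_core_span = max_core_span,
                 s_max_distance = s_max_distance,
                 enumeration_budget = as.integer(enumeration_budget)),
            class = "syntax_grammar")
}

#' @export
print.syntax_grammar <- function(x, ...) {
  cat(sprintf(paste0("<syntax_grammar> order S,F(x1..%d),Z,E%s; ",
                     "Z/E face-to-face; F~Z same strand; ",
                     "core span <= %s bp; S within %s bp\n"),
              x$max_f, if (x$allow_mirror) " (mirror allowed)" else "",
              format(x$max_core_span), format(x$s_max_distance)))
  invisible(x)
}

FLAG_NAMES <- c("complete_core", "s_present", "order_ok", "mirror_used",
                "ze_face_to_face", "fz_same_dir", "span_ok")

# Distance between two 0-based half-open intervals (0 when touching or
# overlapping).
interval_dist <- function(s1, e1, s2, e2) {
  max(0, max(s1, s2) - min(e1, e2))
}

#' Evaluate the grammar rules on one candidate site combination
#'
#' Computes the per-rule flags for a set of member sites (at most one Zic,
#' one Ets, up to `max_f` Foxh1 and one Su(H)/Su(H)-like site, all on one
#' sequence):
#' \describe{
#'   \item{complete_core}{one Zic, one Ets and at least one Foxh1 member.}
#'   \item{ze_face_to_face}{the upstream one of Zic/Ets is on `+` and the
#'     downstream one on `-`, so their 3' ends point at each other.}
#'   \item{fz_same_dir}{the Foxh1 site nearest Zic (ties: upstream Foxh1)
#'     shares Zic's strand.}
#'   \item{order_ok}{the positional class order equals the template
#'     S,F,...,F,Z,E (Su(H) slot only if a Su(H) member exists), or its
#'     reversal when mirroring is allowed.}
#'   \item{mirror_used}{the arrangement reads in the mirrored direction
#'     (Ets upstream of Zic); `FALSE` when the core is incomplete.}
#'   \item{span_ok}{the Foxh1-Zic-Ets core span is at most
#'     `max_core_span`.}
#'   \item{s_present}{a Su(H)/Su(H)-like member exists within
#'     `s_max_distance` of the core bounding interval.}
#' }
#'
#' @param x a `syntax_instance` or a site data.frame (its member sites).
#' @param grammar a [syntax_grammar()] object.
#' @return named logical vector of the seven flags.
#' @export
evaluate_rules <- function(x, grammar = syntax_grammar()) {
  members <- if (inherits(x, "syntax_instance")) x$member_sites else x
  if (!nrow(members)) {
    return(setNames(rep(FALSE, length(FLAG_NAMES)), FLAG_NAMES))
  }
  if (length(unique(members$seq_id)) > 1L) {
    stop("member sites span multiple seq_ids: ",
         paste(unique(members$seq_id), collapse = ", "))
  }
  members <- members[order(members$start, members$end), , drop = FALSE]
  fs <- members[members$tf_class == "F", , drop = FALSE]
  zs <- members[members$tf_class == "Z", , drop = FALSE]
  es <- members[members$tf_class == "E", , drop = FALSE]
  ss <- members[members$tf_class %in% c("S", "S_LIKE"), , drop = FALSE]
  core <- members[members$tf_class %in% CORE_CLASSES, , drop = FALSE]

  complete_core <- nrow(zs) == 1L && nrow(es) == 1L && nrow(fs) >= 1L &&
    nrow(fs) <= grammar$max_f

  core_span <- if (nrow(core)) max(core$end) - min(core$start) else 0L
  span_ok <- core_span <= grammar$max_core_span

  ze_face_to_face <- FALSE
  mirror_used <- FALSE
  if (nrow(zs) == 1L && nrow(es) == 1L) {
    z <- zs[1, ]
    e <- es[1, ]
    ze_face_to_face <-
      (z$start <= e$start && z$strand == "+" && e$strand == "-") ||
      (e$start < z$start && e$strand == "+" && z$strand == "-")
    mirror_used <- complete_core && e$start < z$start
  }

  fz_same_dir <- FALSE
  if (nrow(zs) == 1L && nrow(fs) >= 1L) {
    z <- zs[1, ]
    d <- vapply(seq_len(nrow(fs)), function(i) {
      interval_dist(fs$start[i], fs$end[i], z$start, z$end)
    }, numeric(1))
    near <- which(d == min(d))
    near <- near[which.min(fs$start[near])]  # tie -> upstream Foxh1
    fz_same_dir <- fs$strand[near] == z$strand
  }

  # Positional class order vs. the template, with S_LIKE filling the S slot.
  obs <- members$tf_class
  obs[obs == "S_LIKE"] <- "S"
  template <- c(if (nrow(ss)) "S", rep("F", nrow(fs)),
                if (nrow(zs)) "Z", if (nrow(es)) "E")
  order_ok <- identical(obs, template) ||
    (grammar$allow_mirror && identical(obs, rev(template)))

  s_present <- FALSE
  if (nrow(ss)) {
    if (!nrow(core) || is.infinite(grammar$s_max_distance)) {
      s_present <- TRUE
    } else {
      cs <- min(core$start)
      ce <- max(core$end)
      s_present <- any(vapply(seq_len(nrow(ss)), function(i) {
        interval_dist(ss$start[i], ss$end[i], cs, ce) <=
          grammar$s_max_distance
      }, logical(1)))
    }
  }

  c(complete_core = complete_core, s_present = s_present,
    order_ok = order_ok, mirror_used = mirror_used,
    ze_face_to_face = ze_face_to_face, fz_same_dir = fz_same_dir,
    span_ok = span_ok)
}

#' Classify a flag vector into a compliance tier
#'
#' Precedence: an incomplete Foxh1/Zic/Ets core is `INCOMPLETE`; an
#' orientation violation (Zic/Ets not face-to-face, or the adjacent Foxh1
#' not on Zic's strand) is `SFZE_LIKE_ORIENT`; a core wider than one
#' nucleosome length is `SFZE_LIKE_SPAN`; orientation and span compliant
#' with the template order and a Su(H) site present is `SFZE_FULL`;
#' otherwise (linear order deviates, or Su(H) missing with order intact)
#' `SFZE_LIKE_INVERTED`.
#'
#' @param flags named logical vector as returned by [evaluate_rules()].
#' @return one of `"SFZE_FULL"`, `"SFZE_LIKE_INVERTED"`,
#'   `"SFZE_LIKE_SPAN"`, `"SFZE_LIKE_ORIENT"`, `"INCOMPLETE"`.
#' @export
classify_tier <- function(flags) {
  if (!isTRUE(flags[["complete_core"]])) return("INCOMPLETE")
  if (!(isTRUE(flags[["ze_face_to_face"]]) &&
        isTRUE(flags[["fz_same_dir"]]))) {
    return("SFZE_LIKE_ORIENT")
  }
  if (!isTRUE(flags[["span_ok"]])) return("SFZE_LIKE_SPAN")
  if (isTRUE(flags[["order_ok"]]) && isTRUE(flags[["s_present"]])) {
    return("SFZE_FULL")
  }
  "SFZE_LIKE_INVERTED"
}

#' Build a syntax instance from member sites
#'
#' @param members site data.frame (rows from a [detect_sites()] site set).
#' @param grammar a [syntax_grammar()] object.
#' @return an object of class `syntax_instance` with fields
#'   `member_sites`, `core_span`, `arrangement`, `flags`, `tier`.
#' @export
syntax_instance <- function(members, grammar = syntax_grammar()) {
  members <- members[order(members$start, members$end), , drop = FALSE]
  rownames(members) <- NULL
  flags <- evaluate_rules(members, grammar)
  core <- members[members$tf_class %in% CORE_CLASSES, , drop = FALSE]
  structure(
    list(member_sites = members,
         core_span = if (nrow(core)) max(core$end) - min(core$start) else 0L,
         arrangement = arrangement_string(members),
         flags = flags,
         tier = classify_tier(flags)),
    class = "syntax_instance"
  )
}

#' @export
print.syntax_instance <- function(x, ...) {
  passed <- names(x$flags)[x$flags & names(x$flags) != "mirror_used"]
  cat(sprintf("<syntax_instance> %s  tier=%s  core_span=%d\n  flags: %s\n",
              x$arrangement, x$tier, x$core_span,
              paste(passed, collapse = ", ")))
  invisible(x)
}

#' Enumerate candidate SFZE instances in a site set
#'
#' Forms every combination of exactly one Zic, one Ets and 1..`max_f` Foxh1
#' sites, optionally plus one Su(H)/Su(H)-like site, and evaluates each.
#' Classes absent from the site set are simply left out of the
#' combinations (such candidates carry `complete_core = FALSE` and classify
#' as `INCOMPLETE`). If the number of combinations exceeds the grammar's
#' `enumeration_budget` an error asks for tighter detection thresholds
#' rather than truncating silently.
#'
#' @param s a `site_set` from [detect_sites()] (already deduplicated).
#' @param grammar a [syntax_grammar()] object.
#' @return list of `syntax_instance` objects (empty for an empty site set).
#' @export
enumerate_candidates <- function(s, grammar = syntax_grammar()) {
  stopifnot(inherits(s, "site_set"))
  sites <- s$sites
  if (!nrow(sites)) return(list())
  f_idx <- which(sites$tf_class == "F")
  z_idx <- which(sites$tf_class == "Z")
  e_idx <- which(sites$tf_class == "E")
  s_idx <- which(sites$tf_class %in% c("S", "S_LIKE"))

  f_choices <- if (length(f_idx)) {
    # combn() on positions: a length-1 f_idx must not be read as seq_len(n)
    unlist(lapply(seq_len(min(grammar$max_f, length(f_idx))), function(k) {
      lapply(combn(seq_along(f_idx), k, simplify = FALSE),
             function(pos) f_idx[pos])
    }), recursive = FALSE)
  } else {
    list(integer(0))
  }
  z_choices <- if (length(z_idx)) as.list(z_idx) else list(integer(0))
  e_choices <- if (length(e_idx)) as.list(e_idx) else list(integer(0))
  s_choices <- c(list(integer(0)), as.list(s_idx))

  n_comb <- length(f_choices) * length(z_choices) * length(e_choices) *
    length(s_choices)
  if (n_comb > grammar$enumeration_budget) {
    stop("candidate combinations (", n_comb, ") exceed enumeration budget (",
         grammar$enumeration_budget,
         "); tighten detection thresholds or raise the budget")
  }

  out <- vector("list", n_comb)
  n <- 0L
  for (fc in f_choices) {
    for (zc in z_choices) {
      for (ec in e_choices) {
        for (sc in s_choices) {
          idx <- c(fc, zc, ec, sc)
          if (!length(idx)) next
          n <- n + 1L
          out[[n]] <- syntax_instance(sites[idx, , drop = FALSE], grammar)
        }
      }
    }
  }
  out[seq_len(n)]
}

#' Arrangement notation of a site combination
#'
#' Members left to right with a strand arrow: `"S>"` for a plus-strand
#' Su(H) site, `"<E"` for a minus-strand Ets site, e.g.
#' `"S> F> F> Z> <E"`. Su(H)-like sites print as lowercase `s`, promoter
#' elements as `P`. [parse_arrangement()] inverts the notation.
#'
#' @param x a `syntax_instance` or a site data.frame.
#' @return single string.
#' @export
arrangement_string <- function(x) {
  members <- if (inherits(x, "syntax_instance")) x$member_sites else x
  if (!nrow(members)) return("")
  members <- members[order(members$start, members$end), , drop = FALSE]
  sym <- c(S = "S", S_LIKE = "s", F = "F", Z = "Z", E = "E",
           PROMOTER_ELEMENT = "P")[members$tf_class]
  paste(ifelse(members$strand == "+", paste0(sym, ">"), paste0("<", sym)),
        collapse = " ")
}

#' Parse an arrangement string back into classes and strands
#'
#' @param s arrangement notation as produced by [arrangement_string()].
#' @return data.frame with columns `tf_class` and `strand`, in left-to-right
#'   order.
#' @export
parse_arrangement <- function(s) {
  if (!nzchar(s)) {
    return(data.frame(tf_class = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  cls_map <- c(S = "S", s = "S_LIKE", F = "F", Z = "Z", E = "E",
               P = "PROMOTER_ELEMENT")
  parse_tok <- function(tk) {
    if (grepl("^<.$", tk)) {
      c(cls_map[[substr(tk, 2, 2)]], "-")
    } else if (grepl("^.>$", tk)) {
      c(cls_map[[substr(tk, 1, 1)]], "+")
    } else {
      stop("malformed arrangement token: '", tk, "'")
    }
  }
  parsed <- t(vapply(toks, parse_tok, character(2)))
  data.frame(tf_class = parsed[, 1], strand = parsed[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

tier_rank <- function(tier) {
  length(TIERS) + 1L - match(tier, TIERS)
}

#' Pick the best syntax instance of a region
#'
#' Maximal by tier rank (`SFZE_FULL` highest), then the number of passing
#' rule flags, then the smaller core span, then the larger sum of member
#' scores; remaining ties go to the leftmost start.
#'
#' @param instances list of `syntax_instance` objects from one region.
#' @return the best `syntax_instance`, or `NULL` for an empty list.
#' @export
best_instance <- function(instances) {
  if (!length(instances)) return(NULL)
  rank <- vapply(instances, function(i) tier_rank(i$tier), numeric(1))
  nflags <- vapply(instances, function(i) {
    sum(i$flags[setdiff(FLAG_NAMES, "mirror_used")])
  }, numeric(1))
  span <- vapply(instances, function(i) as.numeric(i$core_span), numeric(1))
  score <- vapply(instances, function(i) sum(i$member_sites$score),
                  numeric(1))
  left <- vapply(instances, function(i) min(i$member_sites$start),
                 numeric(1))
  instances[[order(-rank, -nflags, span, -score, left)[1]]]
}
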