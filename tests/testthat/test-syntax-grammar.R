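# The grammar engine: rule evaluation, tier classification, enumeration.

grammar <- syntax_grammar()

test_that("a textbook direct arrangement passes every rule", {
  members <- rbind(
    site_row(5, 13, "+", "S"),
    site_row(40, 48, "+", "F", motif_id = "f1"),
    site_row(60, 68, "+", "F", motif_id = "f2"),
    site_row(80, 90, "+", "Z"),
    site_row(120, 124, "-", "E"))
  fl <- evaluate_rules(members, grammar)
  expect_true(fl[["complete_core"]])
  expect_true(fl[["order_ok"]])
  expect_false(fl[["mirror_used"]])
  expect_true(fl[["ze_face_to_face"]])
  expect_true(fl[["fz_same_dir"]])
  expect_true(fl[["span_ok"]])
  expect_equal(max(124, 90) - 40, 84)  # core span well under 147
  expect_true(fl[["s_present"]])
  expect_equal(classify_tier(fl), "SFZE_FULL")
})

test_that("same-orientation Zic and Ets violates face-to-face; wide cores violate span", {
  base <- rbind(
    site_row(5, 13, "+", "S"),
    site_row(40, 48, "+", "F", motif_id = "f1"),
    site_row(60, 68, "+", "F", motif_id = "f2"),
    site_row(80, 90, "+", "Z"))
  same_dir <- rbind(base, site_row(120, 124, "+", "E"))
  fl <- evaluate_rules(same_dir, grammar)
  expect_false(fl[["ze_face_to_face"]])
  expect_equal(classify_tier(fl), "SFZE_LIKE_ORIENT")

  wide <- rbind(base, site_row(236, 240, "-", "E"))  # core span 200
  fl <- evaluate_rules(wide, grammar)
  expect_true(fl[["ze_face_to_face"]])
  expect_false(fl[["span_ok"]])
  expect_equal(classify_tier(fl), "SFZE_LIKE_SPAN")
})

test_that("core span boundary sits exactly at one nucleosome length", {
  geom <- function(e_end) rbind(
    site_row(0, 8, "+", "F"),
    site_row(20, 29, "+", "Z"),
    site_row(e_end - 5, e_end, "-", "E"))
  expect_true(evaluate_rules(geom(147), grammar)[["span_ok"]])
  expect_false(evaluate_rules(geom(148), grammar)[["span_ok"]])
})

test_that("the adjacent Foxh1 is the one nearest Zic, ties to the upstream site", {
  members <- rbind(
    site_row(10, 18, "-", "F", motif_id = "far"),
    site_row(60, 68, "+", "F", motif_id = "near"),
    site_row(75, 84, "+", "Z"),
    site_row(100, 104, "-", "E"))
  expect_true(evaluate_rules(members, grammar)[["fz_same_dir"]])
  # equidistant Foxh1 sites: the upstream one decides
  tie <- rbind(
    site_row(60, 68, "-", "F", motif_id = "up"),
    site_row(91, 99, "+", "F", motif_id = "down"),
    site_row(75, 84, "+", "Z"),
    site_row(120, 124, "-", "E"))
  expect_false(evaluate_rules(tie, grammar)[["fz_same_dir"]])
})

test_that("the SEZF partial inversion keeps orientation rules but fails order", {
  members <- rbind(
    site_row(5, 13, "+", "S"),
    site_row(30, 34, "+", "E"),
    site_row(60, 69, "-", "Z"),
    site_row(90, 98, "-", "F"))
  fl <- evaluate_rules(members, grammar)
  expect_true(fl[["ze_face_to_face"]])
  expect_true(fl[["fz_same_dir"]])
  expect_true(fl[["span_ok"]])
  expect_false(fl[["order_ok"]])
  expect_equal(classify_tier(fl), "SFZE_LIKE_INVERTED")
})

test_that("the mirrored arrangement is fully compliant with mirror_used set", {
  members <- rbind(
    site_row(10, 14, "+", "E"),
    site_row(40, 49, "-", "Z"),
    site_row(60, 68, "-", "F", motif_id = "f1"),
    site_row(80, 88, "-", "F", motif_id = "f2"),
    site_row(110, 118, "-", "S"))
  fl <- evaluate_rules(members, grammar)
  expect_true(fl[["order_ok"]])
  expect_true(fl[["mirror_used"]])
  expect_equal(classify_tier(fl), "SFZE_FULL")
  # with mirroring disallowed the same geometry drops to order-deviant
  fl2 <- evaluate_rules(members, syntax_grammar(allow_mirror = FALSE))
  expect_false(fl2[["order_ok"]])
  expect_equal(classify_tier(fl2), "SFZE_LIKE_INVERTED")
})

test_that("missing Su(H) with intact order is not FULL; s_max_distance is honoured", {
  members <- rbind(
    site_row(40, 48, "+", "F"),
    site_row(80, 90, "+", "Z"),
    site_row(120, 124, "-", "E"))
  fl <- evaluate_rules(members, grammar)
  expect_false(fl[["s_present"]])
  expect_true(fl[["order_ok"]])
  expect_equal(classify_tier(fl), "SFZE_LIKE_INVERTED")
  # a distant Su(H)-like site counts by default but not under a tight bound
  with_s <- rbind(site_row(300, 307, "+", "S_LIKE"), members)
  expect_true(evaluate_rules(with_s, grammar)[["s_present"]])
  tight <- syntax_grammar(s_max_distance = 50)
  expect_false(evaluate_rules(with_s, tight)[["s_present"]])
  near_s <- rbind(site_row(0, 7, "+", "S_LIKE"), members)
  expect_true(evaluate_rules(near_s, tight)[["s_present"]])
})

test_that("classification is total and deterministic over the flag lattice", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- sfzescan:::FLAG_NAMES
  tiers <- apply(combos, 1, function(row) classify_tier(as.logical(row) |>
                                                          setNames(names(combos))))
  expect_equal(length(tiers), 128L)
  expect_true(all(tiers %in% c("SFZE_FULL", "SFZE_LIKE_INVERTED",
                               "SFZE_LIKE_SPAN", "SFZE_LIKE_ORIENT",
                               "INCOMPLETE")))
  # precedence spot checks
  expect_equal(classify_tier(c(complete_core = FALSE, s_present = TRUE,
                               order_ok = TRUE, mirror_used = FALSE,
                               ze_face_to_face = FALSE, fz_same_dir = TRUE,
                               span_ok = FALSE)), "INCOMPLETE")
  expect_equal(classify_tier(c(complete_core = TRUE, s_present = TRUE,
                               order_ok = TRUE, mirror_used = FALSE,
                               ze_face_to_face = FALSE, fz_same_dir = TRUE,
                               span_ok = FALSE)), "SFZE_LIKE_ORIENT")
})

test_that("candidate enumeration matches the exhaustive subset oracle", {
  set.seed(91)
  for (trial in 1:8) {
    n <- sample(3:12, 1)
    cls <- sample(c("S", "S_LIKE", "F", "Z", "E"), n, replace = TRUE)
    starts <- sort(sample(0:400, n))
    sites <- do.call(rbind, lapply(seq_len(n), function(i) {
      site_row(starts[i], starts[i] + 8, sample(c("+", "-"), 1), cls[i],
               motif_id = paste0("m", i))
    }))
    ss <- as_site_set(sites)
    inst <- enumerate_candidates(ss, grammar)
    want <- oracle_candidate_subsets(ss$sites, grammar$max_f)
    expect_equal(length(inst), length(want))
    got_keys <- sort(vapply(inst, function(i) {
      paste(sort(paste(i$member_sites$start, i$member_sites$motif_id)),
            collapse = "|")
    }, character(1)))
    want_keys <- sort(vapply(want, function(idx) {
      paste(sort(paste(ss$sites$start[idx], ss$sites$motif_id[idx])),
            collapse = "|")
    }, character(1)))
    expect_equal(got_keys, want_keys)
  }
})

test_that("a site set with one S, two F, one Z, one E yields six candidates", {
  sites <- rbind(
    site_row(5, 13, "+", "S"),
    site_row(40, 48, "+", "F", motif_id = "f1"),
    site_row(60, 68, "+", "F", motif_id = "f2"),
    site_row(80, 90, "+", "Z"),
    site_row(120, 124, "-", "E"))
  inst <- enumerate_candidates(as_site_set(sites), grammar)
  # F choices {f1},{f2},{f1,f2} x 1 Z x 1 E x (no S | S) = 6
  expect_length(inst, 6L)
  expect_equal(length(oracle_candidate_subsets(sites, 2)), 6L)
})

test_that("missing classes yield INCOMPLETE candidates; empty sets yield none", {
  no_z <- rbind(site_row(5, 13, "+", "S"), site_row(40, 48, "+", "F"),
                site_row(120, 124, "-", "E"))
  inst <- enumerate_candidates(as_site_set(no_z), grammar)
  expect_true(length(inst) > 0)
  expect_true(all(vapply(inst, function(i) !i$flags[["complete_core"]],
                         logical(1))))
  expect_true(all(vapply(inst, function(i) i$tier, character(1)) ==
                    "INCOMPLETE"))
  expect_length(enumerate_candidates(as_site_set(site_row(1, 5, "+",
                                                          "E")[0, ])),
                0L)
})

test_that("exceeding the enumeration budget errors instead of truncating", {
  sites <- do.call(rbind, lapply(1:12, function(i) {
    site_row(i * 20, i * 20 + 8, "+",
             c("F", "Z", "E", "S")[((i - 1) %% 4) + 1],
             motif_id = paste0("m", i))
  }))
  tiny <- syntax_grammar(enumeration_budget = 3)
  expect_error(enumerate_candidates(as_site_set(sites), tiny),
               "budget")
})

test_that("arrangement notation round-trips and renders strands as arrows", {
  members <- rbind(
    site_row(5, 13, "+", "S"),
    site_row(40, 48, "+", "F", motif_id = "f1"),
    site_row(60, 68, "+", "F", motif_id = "f2"),
    site_row(80, 90, "+", "Z"),
    site_row(120, 124, "-", "E"))
  expect_equal(arrangement_string(members), "S> F> F> Z> <E")
  mir <- rbind(
    site_row(10, 14, "+", "E"),
    site_row(40, 49, "-", "Z"),
    site_row(60, 68, "-", "F", motif_id = "f1"),
    site_row(80, 88, "-", "F", motif_id = "f2"),
    site_row(110, 118, "-", "S"))
  expect_equal(arrangement_string(mir), "E> <Z <F <F <S")
  expect_equal(arrangement_string(site_row(3, 10, "-", "S_LIKE")), "<s")
  for (s in c("S> F> F> Z> <E", "E> <Z <F <F <S", "<s", "P>")) {
    parsed <- parse_arrangement(s)
    rebuilt <- paste(ifelse(parsed$strand == "+",
                            paste0(c(S = "S", S_LIKE = "s", F = "F",
                                     Z = "Z", E = "E",
                                     PROMOTER_ELEMENT = "P")[parsed$tf_class],
                                   ">"),
                            paste0("<", c(S = "S", S_LIKE = "s", F = "F",
                                          Z = "Z", E = "E",
                                          PROMOTER_ELEMENT = "P")[
                                            parsed$tf_class])),
                     collapse = " ")
    expect_equal(rebuilt, s)
  }
  expect_error(parse_arrangement("S> >F"), "malformed")
})

test_that("best_instance ranks by tier, flags, span, then leftmost start", {
  full_a <- syntax_instance(rbind(
    site_row(5, 13, "+", "S"), site_row(40, 48, "+", "F"),
    site_row(80, 90, "+", "Z"), site_row(120, 124, "-", "E")), grammar)
  full_b <- syntax_instance(rbind(
    site_row(5, 13, "+", "S"), site_row(10, 18, "+", "F"),
    site_row(80, 90, "+", "Z"), site_row(126, 130, "-", "E")), grammar)
  orient <- syntax_instance(rbind(
    site_row(5, 13, "+", "S"), site_row(40, 48, "+", "F"),
    site_row(80, 90, "+", "Z"), site_row(120, 124, "+", "E")), grammar)
  expect_equal(full_a$tier, "SFZE_FULL")
  expect_equal(full_b$tier, "SFZE_FULL")
  expect_equal(orient$tier, "SFZE_LIKE_ORIENT")
  # FULL beats any LIKE tier
  expect_identical(best_instance(list(orient, full_a)), full_a)
  # two FULLs: the tighter core span (84 vs 120) wins
  expect_equal(full_a$core_span, 84L)
  expect_equal(full_b$core_span, 120L)
  expect_identical(best_instance(list(full_b, full_a)), full_a)
  expect_null(best_instance(list()))
})

test_that("rule evaluation rejects members spanning multiple sequences", {
  a <- site_row(0, 8, "+", "F", seq_id = "chr1")
  b <- site_row(20, 29, "+", "Z", seq_id = "chr2")
  expect_error(evaluate_rules(rbind(a, b), grammar), "multiple seq_ids")
})
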