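test_that("motif search finds canonical and variant motifs non-overlappingly", {
  hits <- find_motifs("MKLGGGFAAQRGESAGT")
  expect_equal(hits$oxyanion$position, 4L)
  expect_equal(hits$oxyanion$match, "GGGF")
  expect_equal(hits$catalytic$position, 12L)
  expect_equal(hits$catalytic$match, "GESAG")
  # the ancestral-node variant spellings
  v <- find_motifs("AAGGGLAAGQSAGAA")
  expect_equal(v$oxyanion$match, "GGGL")
  expect_equal(v$catalytic$match, "GQSAG")
  none <- find_motifs("AAAAAA")
  expect_equal(nrow(none$oxyanion), 0)
  expect_equal(nrow(none$catalytic), 0)
  # non-overlapping, left to right
  multi <- find_motifs(paste0("GGGF", "GGGL", "AAA", "GESAG"))
  expect_equal(multi$oxyanion$position, c(1L, 5L))
})

test_that("signal peptide heuristic follows its window rule", {
  pos <- paste0("M", "K", strrep("L", 10), strrep("D", 40))
  call <- predict_signal_peptide(pos)
  expect_true(call$present)
  expect_lte(call$cleavage_guess, 40)
  neg <- paste0("M", strrep("D", 10), strrep("L", 3), strrep("D", 40))
  expect_false(predict_signal_peptide(neg)$present)
  # hydrophobic but no initial methionine
  nom <- paste0("K", strrep("L", 12), strrep("D", 40))
  callm <- predict_signal_peptide(nom)
  expect_false(callm$present)
  expect_equal(callm$reason, "no_initial_methionine")
  short <- predict_signal_peptide("MKLLLLLLLL")
  expect_false(short$present)
  expect_equal(short$reason, "too_short")
})

test_that("signal peptide recall on generated positives is at least 0.95", {
  fx <- make_screening_fixture(n_true = 200, n_decoys = 0, seed = 41)
  calls <- vapply(fx$records, function(r) predict_signal_peptide(r)$present,
                  TRUE)
  expect_gte(mean(calls), 0.95)
})

test_that("lid extraction maps the reference lid onto candidates", {
  ref <- protein_record("ref", paste0(strrep("A", 9), "IVLFIVLFIVL",
                                      strrep("G", 10)),
                        features = list(lid = c(10, 20)))
  # identical candidate: lid is returned verbatim
  same <- extract_lid(protein_record("c", ref$sequence), ref)
  expect_equal(same$sequence, "IVLFIVLFIVL")
  expect_equal(c(same$start, same$end), c(10, 20))
  # candidate with the lid deleted: length 0
  del <- extract_lid(protein_record("d", paste0(strrep("A", 9),
                                                strrep("G", 10))), ref)
  expect_equal(del$length, 0L)
})

test_that("lid extraction recovers the simulated lid (Jaccard >= 0.8)", {
  jac <- vapply(1:50, function(s) {
    fam <- simulate_family(small_cfg(n_leaves = 8, root_length = 150,
                                     lid_start = 80, lid_end = 109,
                                     seed = 400 + s))
    ids <- names(fam$extant)
    ref <- fam$extant[[ids[1]]]
    cand <- fam$extant[[ids[2]]]
    if (is.null(ref$features$lid) || is.null(cand$features$lid))
      return(NA_real_)
    got <- extract_lid(cand, ref)
    if (got$length == 0) return(0)
    a <- seq(got$start, got$end)
    b <- seq(cand$features$lid[1], cand$features$lid[2])
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  expect_gte(median(jac, na.rm = TRUE), 0.8)
})

test_that("screening applies all four criteria with stable reasons", {
  fx <- make_screening_fixture(n_true = 4, n_decoys = 0, seed = 43)
  ref <- fx$reference
  good <- fx$records[[1]]
  rep1 <- screen_candidates(list(good), ref)
  expect_equal(rep1$table$decision, "accepted")
  expect_equal(rep1$table$reasons, "")

  # lid of 19 residues (reference lid is 30): rejected for the lid only
  ch <- strsplit(good$sequence, "")[[1]]
  lid_cols <- 150:179
  short_lid <- protein_record("shortlid",
                              paste(ch[-(lid_cols[1:11])], collapse = ""))
  rep2 <- screen_candidates(list(short_lid), ref)
  expect_lt(rep2$table$lid_length, 20)
  expect_match(rep2$table$reasons, "lid_too_short")
  expect_equal(rep2$table$decision, "rejected")

  # a decoy fails identity, signal and both motifs
  fx2 <- make_screening_fixture(n_true = 2, n_decoys = 1, seed = 44)
  rep3 <- screen_candidates(fx2$records["DECOY01"], fx2$reference)
  expect_match(rep3$table$reasons, "low_identity")
  expect_match(rep3$table$reasons, "no_signal_peptide")

  # injected signal flags override the heuristic
  rep4 <- screen_candidates(list(good), ref,
                            signal_flags = c(TRUE01 = FALSE))
  expect_match(rep4$table$reasons, "no_signal_peptide")
})

test_that("screening is order-independent and monotone in min_lid", {
  fx <- make_screening_fixture(n_true = 5, n_decoys = 5, seed = 45)
  r1 <- screen_candidates(fx$records, fx$reference)
  set.seed(1)
  perm <- sample(length(fx$records))
  r2 <- screen_candidates(fx$records[perm], fx$reference)
  expect_equal(r1$summary, r2$summary)
  d1 <- setNames(r1$table$decision, r1$table$id)
  d2 <- setNames(r2$table$decision, r2$table$id)
  expect_equal(d1[sort(names(d1))], d2[sort(names(d2))])

  accepted_at <- vapply(c(10, 20, 25, 31), function(ml)
    sum(screen_candidates(fx$records, fx$reference,
                          screen_config(min_lid = ml))$table$decision ==
          "accepted"), 0L)
  expect_true(all(diff(accepted_at) <= 0))
})

test_that("planted positives are recovered exactly from the default fixture", {
  fx <- make_screening_fixture(n_true = 5, n_decoys = 5, seed = 46)
  rep <- screen_candidates(fx$records, fx$reference)
  expect_setequal(accepted_ids(rep), fx$labels$id[fx$labels$planted])
})
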