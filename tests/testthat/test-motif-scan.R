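test_that("default PSSM encodes the TBM consensus", {
  pssm <- build_default_pssm()
  w <- pssm$weights
  expect_equal(rowSums(w), rep(1, 8), ignore_attr = TRUE)
  # arginine dominates position 1; glycine is obligatory at position 6
  expect_equal(names(which.max(w["1", ])), "R")
  expect_equal(w["6", "G"], 1)
  expect_equal(sum(w["6", ] > 0), 1)
  # proline is forbidden at position 7, everything else uniform there
  expect_equal(w["7", "P"], 0)
  expect_true(all(abs(w["7", setdiff(colnames(w), "P")] - 1 / 19) < 1e-12))
  # wildcard positions 2 and 3 are uniform and unscored
  expect_true(all(w["2", ] == 1 / 20) && all(w["3", ] == 1 / 20))
  expect_false(any(c(2L, 3L) %in% pssm$scored_positions))
  # acidic residues preferred, basic residues excluded at position 8
  expect_true(all(w["8", c("D", "E")] > w["8", "S"]))
  expect_equal(unname(w["8", c("H", "K", "R")]), rep(0, 3))
})

test_that("TTS scoring matches its definition and the brute-force oracle", {
  pssm <- build_default_pssm()
  expect_equal(tts_score("REEAEGAE", pssm), 1)          # maximal case
  expect_equal(tts_score("RGEPERGS", pssm), 0)          # G6R kills binding
  expect_equal(tts_score("RGEPEGGS", pssm),
               brute_tts("RGEPEGGS", pssm), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    pep <- random_protein(8)
    expect_equal(tts_score(pep, pssm), brute_tts(pep, pssm),
                 tolerance = 1e-12)
  }
  # ambiguity code scores zero at a scored position
  expect_equal(tts_score("XEEAEGAE", pssm), 0)
  expect_error(tts_score("RGEPEGG"), "length 8")
  expect_error(tts_score("RGEPEGGZ"), "invalid residue")
})

test_that("a higher-weight residue at a scored position never lowers the score", {
  pssm <- build_default_pssm()
  set.seed(21)
  for (i in 1:50) {
    pep <- strsplit(random_protein(8), "")[[1]]
    p <- sample(pssm$scored_positions, 1)
    w <- pssm$weights[p, ]
    better <- names(w)[w >= w[pep[p]]]
    pep2 <- pep
    pep2[p] <- sample(better, 1)
    expect_gte(tts_score(paste(pep2, collapse = "")),
               tts_score(paste(pep, collapse = "")))
  }
})

test_that("proteome scanning equals exhaustive window enumeration", {
  pssm <- build_default_pssm()
  recs <- data.frame(id = "MDC1_frag", sequence = "AAAARGEPEGGSAAAA")
  hits <- scan_proteome(recs, pssm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5)
  expect_equal(hits$octapeptide, "RGEPEGGS")
  expect_equal(hits$pos8_class, "S")

  expect_equal(nrow(scan_proteome(recs[0, ], pssm)), 0)
  expect_equal(nrow(scan_proteome(
    data.frame(id = "short", sequence = "RGEPEGG"), pssm)), 0)

  set.seed(31)
  for (i in 1:5) {
    seq <- random_protein(200)
    # a permissive threshold exercises the comparison on many windows
    for (thr in c(0.05, 0.385)) {
      got <- scan_proteome(data.frame(id = "r", sequence = seq),
                           pssm, threshold = thr)
      want <- brute_scan(seq, pssm, thr)
      expect_setequal(got$start, want$start)
      expect_equal(sort(got$tts), sort(want$tts), tolerance = 1e-12)
    }
  }
  # exhaustiveness: threshold 0 returns every length-8 window
  seq <- random_protein(60)
  expect_equal(nrow(scan_proteome(data.frame(id = "r", sequence = seq),
                                  pssm, threshold = 0)), 60 - 7)
})

test_that("scan output is deterministically sorted", {
  pssm <- build_default_pssm()
  recs <- data.frame(
    id = c("B", "A"),
    sequence = c("AAAARGEPEGGSAAAARTQPDGTSAA", "AAAARGEPEGGSAAAA"))
  a <- scan_proteome(recs, pssm)
  b <- scan_proteome(recs, pssm)
  expect_identical(a, b)
  expect_true(all(diff(a$tts) <= 0))
  same <- a$tts[-1] == a$tts[-nrow(a)]
  expect_true(all(!same |
    (a$protein_id[-1] > a$protein_id[-nrow(a)]) |
    (a$protein_id[-1] == a$protein_id[-nrow(a)] &
       a$start[-1] > a$start[-nrow(a)])))
})

test_that("disorder filtering keeps high-disorder motifs and flags unscored proteins", {
  m <- scan_proteome(data.frame(id = "P1", sequence = "AAAARGEPEGGSAAAA"))
  zero <- list(P1 = rep(0, 16))
  one <- list(P1 = rep(1, 16))
  expect_equal(nrow(filter_by_disorder(m, zero, 0.5)), 0)
  expect_equal(filter_by_disorder(m, one, 0.5)$start, m$start)
  # motif covers residues 5..12; mean over a mixed profile
  mixed <- rep(0, 16); mixed[5:8] <- 1                  # mean = 0.5
  expect_equal(nrow(filter_by_disorder(m, list(P1 = mixed), 0.5)), 1)
  mixed[8] <- 0                                          # mean = 0.375
  expect_equal(nrow(filter_by_disorder(m, list(P1 = mixed), 0.5)), 0)
  # proteins without disorder input pass through, flagged unfiltered
  res <- filter_by_disorder(m, list(OTHER = rep(0, 50)), 0.9)
  expect_equal(nrow(res), 1)
  expect_false(res$disorder_filtered)
  expect_error(filter_by_disorder(m, list(P1 = rep(1, 5)), 0.5),
               "shorter")
})

test_that("FASTA and PSSM files round-trip", {
  recs <- data.frame(id = c("P1", "P2"),
                     sequence = c(random_protein(100), random_protein(75)))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  expect_equal(read_fasta(fa), recs)

  pssm <- build_default_pssm()
  tsv <- tempfile(fileext = ".tsv")
  write_tbm_pssm(pssm, tsv)
  back <- read_tbm_pssm(tsv)
  expect_equal(back$weights, pssm$weights, tolerance = 1e-12)
  expect_equal(back$scored_positions, pssm$scored_positions)
})
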