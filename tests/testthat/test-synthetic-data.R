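test_that("planted proteomes are recovered exactly by scanning", {
  spec <- small_spec(seed = 101)
  pro <- make_proteome(spec)
  expect_equal(nrow(pro$truth), 9)          # 5 S + 2 T + 2 Y planted
  hits <- scan_proteome(pro$records, threshold = spec$tts_threshold)
  expect_equal(hits[order(hits$protein_id, hits$start),
                    c("protein_id", "start", "octapeptide")],
               pro$truth[order(pro$truth$protein_id, pro$truth$start),
                         c("protein_id", "start", "octapeptide")],
               ignore_attr = TRUE)
  # zero planted motifs -> scanning finds nothing
  empty <- synthetic_spec(seed = 102, n_proteins = 6L,
                          protein_length = 150L,
                          planted_pos8 = c(S = 0L, T = 0L, Y = 0L))
  pro0 <- make_proteome(empty)
  expect_equal(nrow(scan_proteome(pro0$records)), 0)
})

test_that("the generator is bitwise reproducible per seed", {
  a <- make_proteome(small_spec(seed = 103))
  b <- make_proteome(small_spec(seed = 103))
  expect_identical(a, b)
  c <- make_proteome(small_spec(seed = 104))
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("planted placement constraints are enforced", {
  bad <- synthetic_spec(seed = 105, n_proteins = 2L,
                        protein_length = 50L,
                        planted_motifs = data.frame(
                          host = 1L, start = 48L,
                          octapeptide = "RGEPEGGS"))
  expect_error(make_proteome(bad), "does not fit")
  overlap <- synthetic_spec(seed = 105, n_proteins = 2L,
                            protein_length = 50L,
                            planted_motifs = data.frame(
                              host = c(1L, 1L), start = c(10L, 14L),
                              octapeptide = "RGEPEGGS"))
  expect_error(make_proteome(overlap), "overlapping")
})

test_that("phospho tables reproduce the planted arm composition", {
  spec <- small_spec(seed = 106, phospho_rate_background = 0,
                     planted_pos8_prob = 1)
  pro <- make_proteome(spec)
  ph <- make_phospho_table(spec, pro)
  expect_equal(unname(ph$truth$arm_motif_counts), c(5L, 2L, 2L))
  # the pipeline census over the generated events agrees with truth
  hits <- scan_proteome(pro$records, threshold = spec$tts_threshold)
  cen <- census_by_arm(map_events_to_motifs(hits, ph$events))
  expect_equal(cen$motif_counts, ph$truth$arm_motif_counts)
  expect_equal(sort(cen$proteins_pS8_pT8),
               sort(ph$truth$phospho8_hosts_st))

  # no background, no planting -> empty table
  off <- small_spec(seed = 107, phospho_rate_background = 0,
                    planted_pos8_prob = 0)
  expect_equal(nrow(make_phospho_table(off, make_proteome(off))$events),
               0)
})

test_that("a strongly planted term is the top enriched hit with fold > 4", {
  spec <- synthetic_spec(seed = 108, n_proteins = 80L,
                         protein_length = 250L,
                         planted_pos8 = c(S = 8L, T = 2L, Y = 1L),
                         phospho_rate_background = 0,
                         planted_term = list(
                           term_id = "T0001",
                           term_name = "planted (synthetic)",
                           member_prob_phospho = 1,
                           member_prob_background = 0.05))
  pro <- make_proteome(spec)
  ph <- make_phospho_table(spec, pro)
  ann <- make_term_annotations(spec, pro, ph)
  res <- enrich(ph$truth$phospho8_hosts_st, ann$annotations,
                population = pro$records$id)
  expect_equal(res$term_id[1], "T0001")
  expect_gt(res$fold[1], 4)
  expect_lt(res$p[1], res$p[2])
})

test_that("toy structure pairs carry exact transform and shift truth", {
  toys <- make_toy_structures(seed = 109, shift = 1.3)
  align <- list(resno = setdiff(1:12, toys$probe_res), elety = "CA")
  d <- ca_displacement(toys$model_a, toys$model_b, align,
                       probe_a = list(resno = toys$probe_res,
                                      elety = "CA"))
  expect_equal(as.numeric(d), 1.3, tolerance = 1e-6)
  # recovered rotation inverts the applied one
  sup <- attr(d, "superposition")
  expect_equal(sup$rotation %*% toys$rotation, diag(3),
               tolerance = 1e-9)
  zero <- make_toy_structures(seed = 110, shift = 0)
  d0 <- ca_displacement(zero$model_a, zero$model_b, align,
                        probe_a = list(resno = zero$probe_res,
                                       elety = "CA"))
  expect_equal(as.numeric(d0), 0, tolerance = 1e-9)
})

test_that("simulate_dataset writes a reproducible, self-consistent bundle", {
  spec <- small_spec(seed = 111)
  d1 <- file.path(tempdir(), "synth1")
  d2 <- file.path(tempdir(), "synth2")
  out1 <- simulate_dataset(spec, d1)
  out2 <- simulate_dataset(spec, d2)
  for (p in c("proteome.fasta", "phospho.tsv", "annotations.tsv",
              "truth.json", "toy_a.pdb")) {
    expect_identical(readLines(file.path(d1, p)),
                     readLines(file.path(d2, p)),
                     label = p)
  }
  # plate files round-trip through the FP pipeline to the planted Kd
  plate <- read_fp_plate(out1$paths$plates[1])
  tt <- baseline_correct(plate)
  fit <- fit_one_site_total(tt)
  expect_true(fit$converged)
  kd_true <- spec$fp_specs$kd[1]
  expect_lt(abs(fit$kd - kd_true) / kd_true, 0.5)   # noisy single series
  unlink(c(d1, d2), recursive = TRUE)
})
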