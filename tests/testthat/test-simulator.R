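test_that("no continuation yields exactly one repeat unit", {
  set.seed(1)
  prod <- simulate_product(eco3_template(), eco3_pattern(),
                           sim_config(p_continue = 0))
  expect_identical(prod$sequence, ECO3_MOTIF)
  expect_identical(prod$n_repeats, 1L)
  expect_true(prod$protein_primed_5prime)
})

test_that("deterministic cycling emits exact tandem concatemers", {
  set.seed(1)
  prod <- simulate_product(eco3_template(), eco3_pattern(), det_config(5))
  expect_identical(prod$sequence, strrep(ECO3_MOTIF, 5))
  expect_identical(prod$n_repeats, 5L)
  ## all realignments at the canonical A' (template position 10)
  expect_identical(prod$realign_sites, rep(10L, 4))
})

test_that("simulation is reproducible under a config seed", {
  cfg <- det_config(50, p_continue = 0.9)
  cfg$seed <- 77L
  p1 <- simulate_product(eco3_template(), eco3_pattern(), cfg)
  p2 <- simulate_product(eco3_template(), eco3_pattern(), cfg)
  expect_identical(p1, p2)
})

test_that("mutating A or A' alone abolishes repeat addition; joint mutation restores it", {
  ## complement-substitute the first two bases of A (positions 1-2) or of
  ## A' (positions 10-11); defaults demand Watson-Crick pairing there
  tpl_a <- ncrna_template("mutA", mutate_complement(ECO3_LOOP, 1:2),
                          loop_interval = c(1, 13))
  tpl_ap <- ncrna_template("mutAp", mutate_complement(ECO3_LOOP, 10:11),
                           loop_interval = c(1, 13))
  tpl_both <- ncrna_template("mutBoth",
                             mutate_complement(ECO3_LOOP, c(1:4, 10:13)),
                             loop_interval = c(1, 13))
  cfg <- sim_config(seq_error_rate = 0)
  set.seed(202)
  n_single_a <- sum(vapply(1:200, function(i)
    simulate_product(tpl_a, eco3_pattern(), cfg)$n_repeats, integer(1)) == 1L)
  n_single_ap <- sum(vapply(1:200, function(i)
    simulate_product(tpl_ap, eco3_pattern(), cfg)$n_repeats, integer(1)) == 1L)
  expect_gte(n_single_a / 200, 0.95)
  expect_gte(n_single_ap / 200, 0.95)

  ## compensatory double mutant: repeats of the *mutated* motif
  mut_motif <- predict_repeat_motif(eco3_pattern(), tpl_both)
  expect_false(mut_motif == ECO3_MOTIF)
  set.seed(303)
  prods <- lapply(1:200, function(i)
    simulate_product(tpl_both, eco3_pattern(), cfg))
  n_rep <- vapply(prods, `[[`, integer(1), "n_repeats")
  expect_gt(mean(n_rep > 1), 0.5)
  multi <- prods[n_rep > 1][[1]]
  expect_identical(multi$sequence, strrep(mut_motif, multi$n_repeats))
})

test_that("expected repeat count is monotone in continuation and realignment success", {
  tpl <- eco3_template(); pat <- eco3_pattern()
  mean_reps <- function(p_cont, p4) {
    cfg <- sim_config(p_continue = p_cont, seq_error_rate = 0,
                      realign_rules = realign_rules(
                        p_success_by_matchlen = c("2" = 0.05, "3" = 0.5,
                                                  "4" = p4)))
    mean(vapply(1:300, function(i)
      simulate_product(tpl, pat, cfg)$n_repeats, integer(1)))
  }
  set.seed(404)
  p_grid <- c(0.2, 0.5, 0.8, 0.95)
  by_cont <- vapply(p_grid, mean_reps, numeric(1), p4 = 0.95)
  by_succ <- vapply(p_grid, function(p) mean_reps(0.95, p), numeric(1))
  expect_gt(cor(p_grid, by_cont, method = "spearman"), 0)
  expect_gt(cor(p_grid, by_succ, method = "spearman"), 0)
})

test_that("template length attenuates repeat addition (10-mer reduced, 20-mer lost)", {
  ## replace the native 5-mer B with synthetic 10-mer / 20-mer spacers
  set.seed(505)
  multi_frac <- function(b, n = 400) {
    seq <- paste0("CAAU", b, "CAAU")
    tpl <- ncrna_template("b", seq, loop_interval = c(1, nchar(seq)))
    pat <- list(a_start = 1L, a_len = 4L, b_len = nchar(b))
    cfg <- sim_config(seq_error_rate = 0)
    mean(vapply(1:n, function(i)
      simulate_product(tpl, pat, cfg)$n_repeats, integer(1)) > 1L)
  }
  native <- multi_frac("GAUUC")
  b10 <- multi_frac(random_rna(10))
  b20 <- multi_frac(random_rna(20), n = 3000)  # resolves ~0.6% vs the 1% bound
  expect_gt(native, b10)
  expect_gt(b10, 0)
  expect_lt(b10, 0.8 * native)
  expect_lt(b20, 0.01)
})

test_that("a cryptic re-annealing site inside B yields mixed repeat-unit lengths", {
  ## B carries an internal copy of A (template positions 6-9), which pairs
  ## the primer 3' tail one base deeper than the canonical A' and therefore
  ## captures the resets: products mix the full-length first unit with
  ## short units, unlike the clean template
  seq <- paste0("CAAU", "GCAAUGG", "CAAU")
  tpl <- ncrna_template("cryptic", seq, loop_interval = c(1, nchar(seq)))
  pat <- list(a_start = 1L, a_len = 4L, b_len = 7L)
  set.seed(606)
  prod <- simulate_product(tpl, pat, det_config(8))
  expect_true(any(prod$realign_sites != 12L))   # non-canonical resets
  ## unit lengths are irregular: total length is not n_repeats * unit
  expect_false(nchar(prod$sequence) == prod$n_repeats * 11L)
  full_motif <- predict_repeat_motif(pat, tpl)
  expect_false(prod$sequence == strrep(full_motif, prod$n_repeats))

  ## clean template of the same geometry resets only at the canonical A'
  seq2 <- paste0("CAAU", "GGCGCGG", "CAAU")
  tpl2 <- ncrna_template("clean", seq2, loop_interval = c(1, nchar(seq2)))
  set.seed(607)
  prod2 <- simulate_product(tpl2, pat, det_config(8))
  expect_true(all(prod2$realign_sites == 12L))
  expect_identical(prod2$sequence,
                   strrep(predict_repeat_motif(pat, tpl2), prod2$n_repeats))
})

test_that("read generation is reproducible, labeled, and binomially mixed", {
  tpl <- eco3_template(); pat <- eco3_pattern()
  set.seed(9)
  ref <- random_reference(1000)
  cfg <- sim_config(seed = 123L, read_len = 100L)
  d1 <- generate_dataset(tpl, pat, ref, cfg, 500, "WT")
  d2 <- generate_dataset(tpl, pat, ref, cfg, 500, "WT")
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(d1, f1); write_fastq(d2, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## RT-dead: background only
  dd <- generate_dataset(NULL, NULL, ref, cfg, 200, "RT_dead")
  expect_true(all(dd$truth == "background"))
  expect_identical(attr(dd, "n_reference_mapping"), 200L)

  ## repeat-read fraction within +/- 2% of 1 - background_fraction
  cfg_big <- sim_config(seed = 321L, seq_error_rate = 0)
  big <- generate_dataset(tpl, pat, ref, cfg_big, 10000, "WT")
  frac <- mean(big$truth == "repeat_product")
  expect_lt(abs(frac - 0.30), 0.02)

  ## reads never exceed the configured read length
  expect_lte(max(nchar(big$sequence)), 150L)
})

test_that("error-free repeat reads are substrings of motif concatemers", {
  tpl <- eco3_template(); pat <- eco3_pattern()
  set.seed(10)
  ref <- random_reference(500)
  cfg <- sim_config(seed = 42L, seq_error_rate = 0)
  ds <- generate_dataset(tpl, pat, ref, cfg, 400, "WT")
  rep_reads <- ds$sequence[ds$truth == "repeat_product"]
  concat <- strrep(ECO3_MOTIF, ceiling(150 / 9) + 2)
  rc_concat <- o_revcomp_dna(concat)
  expect_true(all(vapply(rep_reads, function(r)
    grepl(r, concat, fixed = TRUE) || grepl(r, rc_concat, fixed = TRUE),
    logical(1))))
})
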