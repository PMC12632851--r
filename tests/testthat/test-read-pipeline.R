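make_rs <- function(seqs, n_ref = 1000L, read_len = NULL) {
  read_set(data.frame(id = paste0("r", seq_along(seqs)), sequence = seqs,
                      condition = "WT", truth = NA_character_,
                      stringsAsFactors = FALSE),
           n_reference_mapping = n_ref, read_len = read_len)
}

test_that("partitioning matches generator truth on error-free data", {
  set.seed(21)
  ref <- random_reference(2000)
  tpl <- eco3_template()
  cfg <- sim_config(seed = 5L, seq_error_rate = 0)
  ds <- generate_dataset(tpl, eco3_pattern(), ref, cfg, 600, "WT")
  part <- partition_unmapped(ds, ref)
  expect_setequal(part$mapped$truth, "background")
  expect_setequal(part$unmapped$truth, "repeat_product")
  expect_identical(nrow(part$mapped) + nrow(part$unmapped), 600L)
  ## both sets carry the mapped count for normalization
  expect_identical(attr(part$mapped, "n_reference_mapping"),
                   nrow(part$mapped))
  expect_identical(attr(part$unmapped, "n_reference_mapping"),
                   nrow(part$mapped))
  ## containment basics
  direct <- make_rs(c(substr(ref, 101, 250), strrep(ECO3_MOTIF, 16)))
  p2 <- partition_unmapped(direct, ref)
  expect_identical(p2$mapped$id, "r1")
  expect_identical(p2$unmapped$id, "r2")
  expect_warning(partition_unmapped(direct, ref, min_anchor = 9),
                 "spurious")
})

test_that("hit scanning is exact, non-overlapping and strand-aware", {
  expect_identical(as.integer(scan_hits(strrep(ECO3_MOTIF, 3), ECO3_MOTIF)),
                   c(0L, 9L, 18L))
  expect_identical(length(scan_hits("ACGTACGTACGT", ECO3_MOTIF)), 0L)
  ## reverse-complement reads give the same hits via orientation choice
  rc_read <- o_revcomp_dna(strrep(ECO3_MOTIF, 3))
  h <- scan_hits(rc_read, ECO3_MOTIF)
  expect_identical(as.integer(h), c(0L, 9L, 18L))
  expect_identical(attr(h, "orientation"), "-")
  ## non-overlapping greedy: AAA in AAAAA -> one hit at 0
  expect_identical(as.integer(scan_hits("AAAAA", "AAA")), 0L)
  ## brute-force oracle on random reads
  set.seed(77)
  for (i in 1:50) {
    read <- random_dna_str(sample(20:120, 1))
    motif <- random_dna_str(sample(2:4, 1))
    expect_identical(as.integer(scan_hits(read, motif)),
                     as.integer(oracle_scan(read, motif)),
                     label = paste(read, motif))
  }
  ## Hamming-tolerant scanning
  expect_identical(as.integer(scan_hits("GAGTCATTG", ECO3_MOTIF,
                                        max_mismatch = 1)), 0L)
})

test_that("motif position graphs count shifted hit starts and normalize by CPM", {
  rs <- make_rs(strrep(ECO3_MOTIF, 3), n_ref = 1000L, read_len = 27L)
  g <- position_graph(rs, ECO3_MOTIF)
  expect_identical(which(g$counts > 0) - 1L, c(0L, 9L, 18L))
  expect_identical(g$counts[1], 1L)
  expect_equal(g$cpm, g$counts * 1e6 / 1000)

  ## brute-force oracle on an arbitrary seeded set
  set.seed(31)
  seqs <- c(replicate(40, random_dna_str(60)),
            replicate(10, paste0(random_dna_str(5), strrep("ACGTT", 8))))
  rs2 <- make_rs(seqs, n_ref = 500L, read_len = 60L)
  g2 <- position_graph(rs2, "ACGTT")
  expect_identical(g2$counts, oracle_position_counts(seqs, "ACGTT", 60L))
  ## counts[0] equals the number of motif-containing reads
  expect_identical(g2$counts[1],
                   sum(vapply(seqs, function(s)
                     length(oracle_scan(s, "ACGTT")) > 0, logical(1))))
  ## normalized quantities scale exactly inversely with the denominator
  attr(rs2, "n_reference_mapping") <- 250L
  g3 <- position_graph(rs2, "ACGTT")
  expect_equal(g3$cpm, 2 * g2$cpm)
  ## zero denominator: raw counts only
  attr(rs2, "n_reference_mapping") <- 0L
  expect_message(g0 <- position_graph(rs2, "ACGTT"), "cpm undefined")
  expect_null(g0$cpm)
  expect_identical(g0$counts, g2$counts)
})

test_that("error-free simulated WT reads show pure 9-nt periodicity", {
  set.seed(41)
  ref <- random_reference(2000)
  cfg <- sim_config(seed = 6L, seq_error_rate = 0)
  ds <- generate_dataset(eco3_template(), eco3_pattern(), ref, cfg, 800, "WT")
  part <- partition_unmapped(ds, ref)
  g <- position_graph(part$unmapped, ECO3_MOTIF)
  nz <- which(g$counts > 0) - 1L
  expect_true(all(nz %% 9L == 0L))
  expect_identical(estimate_period(g), 9L)
})

test_that("longest-run histograms respect exact spacing and conservation", {
  ## a 150-nt read of perfect repeats attains the 16-repeat ceiling
  full <- substr(strrep(ECO3_MOTIF, 17), 1, 150)
  h <- repeat_run_histogram(make_rs(full, read_len = 150L), ECO3_MOTIF)
  expect_identical(h$runs, 16L)
  ## runs of 5 and 3 separated by a 4-nt spacer -> longest run 5
  read53 <- paste0(strrep(ECO3_MOTIF, 5), "ACGT", strrep(ECO3_MOTIF, 3))
  h53 <- repeat_run_histogram(make_rs(read53), ECO3_MOTIF)
  expect_identical(h53$runs, 5L)
  ## motif-free read -> 0
  expect_identical(repeat_run_histogram(make_rs("ACGTACGTACGT"),
                                        ECO3_MOTIF)$runs, 0L)
  ## conservation: bins sum to the number of reads; oracle equivalence
  set.seed(51)
  seqs <- vapply(1:60, function(i) {
    k <- sample(0:4, 1)
    paste0(random_dna_str(sample(1:20, 1)), strrep("GATTACA", k),
           random_dna_str(sample(1:20, 1)))
  }, character(1))
  hh <- repeat_run_histogram(make_rs(seqs), "GATTACA")
  expect_identical(sum(hh$bins), 60L)
  want <- vapply(seqs, function(s)
    oracle_longest_run(oracle_scan(s, "GATTACA"), 7L), integer(1))
  expect_identical(hh$runs, unname(want))
  expect_identical(hh$median_run, median(want))
  ## interrupted units can be bridged when allowed
  h_skip <- repeat_run_histogram(make_rs(paste0(strrep(ECO3_MOTIF, 2),
                                                ECO3_MOTIF, # exact spacing
                                                strrep("N", 0))),
                                 ECO3_MOTIF)
  expect_identical(h_skip$runs, 3L)
  gap_read <- paste0(ECO3_MOTIF, strrep("ACGTACGTA", 1), ECO3_MOTIF)
  expect_identical(repeat_run_histogram(make_rs(gap_read),
                                        ECO3_MOTIF)$runs, 1L)
  expect_identical(repeat_run_histogram(make_rs(gap_read), ECO3_MOTIF,
                                        max_skip = 1)$runs, 2L)
})

test_that("min-repeat read counts are CPM-normalized and truth-consistent", {
  seqs <- c(replicate(4, strrep(ECO3_MOTIF, 4)),
            replicate(6, random_dna_str(50)))
  rs <- make_rs(seqs, n_ref = 1e6L)
  expect_equal(count_min_repeat_reads(rs, ECO3_MOTIF, k = 3), 4.0)
  expect_error(count_min_repeat_reads(rs, ECO3_MOTIF, k = 0), "k must be")
  rs0 <- make_rs(seqs, n_ref = 0L)
  expect_error(count_min_repeat_reads(rs0, ECO3_MOTIF), "normalization")

  ## RT-dead background contains no motif runs
  set.seed(61)
  ref <- random_reference(2000)
  dd <- generate_dataset(NULL, NULL, ref, sim_config(seed = 8L), 500,
                         "RT_dead")
  expect_equal(count_min_repeat_reads(dd, ECO3_MOTIF), 0)
})

test_that("context logos carry the direct-repeat signature", {
  ## tandem repeats: flank columns reproduce the motif shifted by one period
  rs <- make_rs(replicate(20, strrep(ECO3_MOTIF, 10)), read_len = 90L)
  lg <- context_logo(rs, ECO3_MOTIF, flank = 9)
  cons <- rownames(lg$pfm)[apply(lg$pfm, 2, which.max)]
  expect_identical(paste(cons, collapse = ""), strrep(ECO3_MOTIF, 3))
  ## column sums equal the number of sites covering each column
  inner <- lg$pfm[, as.integer(colnames(lg$pfm)) %in% 0:8]
  expect_true(all(colSums(inner) == lg$n_sites))
  ## brute-force column-sum check with edge truncation
  set.seed(71)
  seqs <- replicate(30, paste0(random_dna_str(sample(0:12, 1)), "GATTACA",
                               random_dna_str(sample(0:12, 1))))
  lg2 <- context_logo(make_rs(seqs), "GATTACA", flank = 5)
  sites <- lapply(seqs, oracle_scan, motif = "GATTACA")
  want <- integer(7 + 10)
  for (i in seq_along(seqs)) {
    for (pos in sites[[i]]) {
      for (col in seq_len(17)) {
        p <- pos - 5 + col - 1
        if (p >= 0 && p < nchar(seqs[i])) want[col] <- want[col] + 1L
      }
    }
  }
  expect_identical(as.integer(colSums(lg2$pfm)), want)
  ## isolated hits with random flanks: flank columns near-uniform
  set.seed(81)
  iso <- replicate(400, paste0(random_dna_str(9), "GATTACA",
                               random_dna_str(9)))
  lg3 <- context_logo(make_rs(iso), "GATTACA", flank = 9)
  flank_cols <- lg3$pfm[, as.integer(colnames(lg3$pfm)) < 0]
  freqs <- sweep(flank_cols, 2, colSums(flank_cols), "/")
  expect_lt(max(abs(freqs - 0.25)), 0.12)
})

test_that("period estimation takes the weighted spacing mode, ties to smaller", {
  mk_graph <- function(counts, read_len = length(counts)) {
    rs <- make_rs("A", read_len = read_len)  # shell; counts injected below
    g <- position_graph(rs, "CCC")
    g$counts <- as.integer(counts)
    g$position <- seq_along(counts) - 1L
    g
  }
  g9 <- mk_graph(as.integer(seq(0, 149) %% 9 == 0))
  expect_identical(estimate_period(g9), 9L)
  g6 <- mk_graph(c(1, rep(0, 5), 1))
  expect_identical(estimate_period(g6), 6L)
  expect_error(estimate_period(mk_graph(c(1, 0, 0))), "undefined")
  ## mixed-period graph equals brute-force spacing tally
  set.seed(91)
  for (i in 1:20) {
    counts <- integer(80)
    nz <- sort(sample(0:79, sample(5:15, 1)))
    counts[nz + 1] <- sample(1:50, length(nz), replace = TRUE)
    expect_identical(estimate_period(mk_graph(counts)),
                     oracle_period(counts))
  }
})

test_that("pipeline quantities are invariant to read order and global reverse complement", {
  set.seed(111)
  ref <- random_reference(1500)
  cfg <- sim_config(seed = 13L)
  ds <- generate_dataset(eco3_template(), eco3_pattern(), ref, cfg, 400, "WT")
  part <- partition_unmapped(ds, ref)
  un <- part$unmapped
  g <- position_graph(un, ECO3_MOTIF)
  h <- repeat_run_histogram(un, ECO3_MOTIF)

  shuffled <- un[sample(nrow(un)), , drop = FALSE]
  attributes(shuffled)[c("n_reference_mapping", "read_len")] <-
    attributes(un)[c("n_reference_mapping", "read_len")]
  g_sh <- position_graph(shuffled, ECO3_MOTIF)
  expect_identical(g_sh$counts, g$counts)
  expect_identical(sort(repeat_run_histogram(shuffled, ECO3_MOTIF)$runs),
                   sort(h$runs))

  flipped <- un
  flipped$sequence <- o_revcomp_dna_vec(un$sequence)
  g_fl <- position_graph(flipped, ECO3_MOTIF)
  expect_identical(g_fl$counts, g$counts)
  expect_identical(repeat_run_histogram(flipped, ECO3_MOTIF)$runs, h$runs)
})
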