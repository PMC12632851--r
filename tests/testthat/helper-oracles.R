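## Independent brute-force oracles and fixture builders. Deliberately naive
## implementations that never share code with the package.

o_revcomp_dna <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(unname(c(A = "T", C = "G", G = "C", T = "A")[ch]), collapse = "")
}

o_revcomp_dna_vec <- function(x) vapply(x, o_revcomp_dna, character(1),
                                        USE.NAMES = FALSE)

## cDNA encoded by an RNA segment: reverse complement, RNA -> DNA
o_rna_to_cdna <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(unname(c(A = "T", C = "G", G = "C", U = "A")[ch]), collapse = "")
}

## RNA template segment encoding a DNA motif, plus the A' copy
o_design <- function(motif, a_len) {
  ch <- rev(strsplit(motif, "", fixed = TRUE)[[1]])
  ab <- paste(unname(c(A = "U", C = "G", G = "C", T = "A")[ch]),
              collapse = "")
  paste0(ab, substr(ab, 1, a_len))
}

## exhaustive enumeration of A-B-A' patterns over all (a_start, a_len,
## b_len) triples, with the leftward-maximality filter and rank order
oracle_aba <- function(seq, min_a = 2, max_a = 10, min_motif = 4,
                       max_motif = 30, s = 1, e = nchar(seq)) {
  sub <- function(i, j) substr(seq, i, j)
  rows <- list()
  for (a_start in s:e) {
    for (a_len in min_a:max_a) {
      for (b_len in 0:max(0, e - s)) {
        d <- a_len + b_len
        if (d < min_motif || d > max_motif) next
        ap <- a_start + d
        if (ap + a_len - 1 > e) next
        if (sub(a_start, a_start + a_len - 1) != sub(ap, ap + a_len - 1))
          next
        if (a_start - 1 >= s && b_len >= 1 && a_len + 1 <= max_a &&
            sub(a_start - 1, a_start - 1) == sub(ap - 1, ap - 1))
          next   # A extendable one base leftward at both sites
        rows[[length(rows) + 1]] <-
          data.frame(a_start = a_start, a_len = a_len, b_len = b_len,
                     aprime_start = ap)
      }
    }
  }
  if (!length(rows))
    return(data.frame(a_start = integer(0), a_len = integer(0),
                      b_len = integer(0), aprime_start = integer(0),
                      motif_dna = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$a_len, out$b_len, out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out$motif_dna <- vapply(seq_len(nrow(out)), function(i)
    o_rna_to_cdna(substr(seq, out$a_start[i], out$aprime_start[i] - 1)),
    character(1))
  out
}

## forward-strand non-overlapping greedy scan, 0-based starts
oracle_scan_fwd <- function(read, motif) {
  w <- nchar(motif)
  out <- integer(0)
  i <- 1
  while (i <= nchar(read) - w + 1) {
    if (substr(read, i, i + w - 1) == motif) {
      out <- c(out, i - 1)
      i <- i + w
    } else i <- i + 1
  }
  out
}

## both-strand scan with the more-hits orientation (ties -> forward)
oracle_scan <- function(read, motif) {
  f <- oracle_scan_fwd(read, motif)
  r <- oracle_scan_fwd(o_revcomp_dna(read), motif)
  if (length(r) > length(f)) r else f
}

oracle_longest_run <- function(hits, unit) {
  if (!length(hits)) return(0L)
  best <- 1L; run <- 1L
  for (i in seq_along(hits)[-1]) {
    run <- if (hits[i] - hits[i - 1] == unit) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

oracle_position_counts <- function(reads, motif, read_len) {
  counts <- integer(read_len)
  for (r in reads) {
    h <- oracle_scan(r, motif)
    if (!length(h)) next
    rel <- h - h[1]
    rel <- rel[rel < read_len]
    counts[rel + 1] <- counts[rel + 1] + 1L
  }
  counts
}

oracle_period <- function(counts) {
  nz <- which(counts > 0) - 1
  d <- diff(nz)
  w <- pmin(counts[nz[-length(nz)] + 1], counts[nz[-1] + 1])
  tal <- tapply(w, d, sum)
  min(as.integer(names(tal)[tal == max(tal)]))
}

random_rna <- function(n)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
random_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## --- canonical Eco3-like fixture -----------------------------------------
## Template loop CAAU|GAUUC|CAAU: A = CAAU, B = GAUUC, A' = CAAU, encoding
## the 9-nt repeat GAATCATTG.
ECO3_LOOP <- "CAAUGAUUCCAAU"
ECO3_MOTIF <- "GAATCATTG"
eco3_template <- function()
  ncrna_template("eco3", ECO3_LOOP, loop_interval = c(1L, 13L))
eco3_pattern <- function() list(a_start = 1L, a_len = 4L, b_len = 5L)

## Designed-template fixture whose embedded pattern is, per the oracle, the
## unique top-ranked pattern of the segment (rejection sampling keeps the
## ground truth unambiguous; the oracle, not the implementation, vouches
## for it).
make_unambiguous_design <- function(motif_len, a_len) {
  repeat {
    motif <- random_dna_str(motif_len)
    seg <- o_design(motif, a_len)
    orc <- oracle_aba(seg)
    if (nrow(orc) >= 1 && orc$a_start[1] == 1 && orc$a_len[1] == a_len &&
        orc$b_len[1] == motif_len - a_len)
      return(list(motif = motif, segment = seg))
  }
}

## deterministic simulator settings: every eligible cycle succeeds
det_config <- function(max_cycles, p_continue = 1) {
  sim_config(p_continue = p_continue, max_cycles = max_cycles,
             realign_rules = realign_rules(
               p_success_by_matchlen = c("2" = 1, "3" = 1, "4" = 1)),
             template_len_midpoint = 1000, seq_error_rate = 0)
}

## complement-substitute positions of an RNA string (mutational series)
mutate_complement <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  ch[positions] <- unname(comp[ch[positions]])
  paste(ch, collapse = "")
}
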