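## Differential k-mer motif discovery between WT and control unmapped reads.
## A transparent replacement for black-box motif discovery: per-read k-mer
## containment counts, a one-sided two-proportion test per k-mer, greedy
## clustering of shift-overlapping / reverse-complement k-mers, and a
## support-based choice of consensus width within each cluster.

#' @import data.table
NULL

## per-read containment counts of canonical k-mers (k-mer or its reverse
## complement, whichever is lexicographically smaller) of one width
.kmer_containment <- function(seqs, w) {
  lens <- nchar(seqs)
  max_off <- max(lens) - w + 1L
  if (max_off < 1L)
    return(data.table::data.table(kmer = character(0), n = integer(0)))
  pieces <- vector("list", max_off)
  for (j in seq_len(max_off)) {
    ok <- lens >= j + w - 1L
    if (!any(ok)) break
    pieces[[j]] <- data.table::data.table(read = which(ok),
                                          kmer = substr(seqs[ok], j, j + w - 1L))
  }
  dt <- data.table::rbindlist(pieces)
  dt <- unique(dt)
  uk <- unique(dt$kmer)
  rc <- .revcomp_dna(uk)
  canon <- ifelse(uk <= rc, uk, rc)
  dt[, "kmer" := canon[match(dt$kmer, uk)]]
  dt <- unique(dt)
  dt[, list(n = .N), by = "kmer"]
}

## one-sided two-proportion z test (H1: p_wt > p_ctrl); returns log p
.two_prop_logp <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pmax(pp * (1 - pp) * (1 / n1 + 1 / n2), .Machine$double.eps))
  z <- (p1 - p2) / se
  list(z = z, logp = stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

## longest exact ungapped overlap between strings a and b over all offsets
## (containment counts as full overlap of the shorter)
.max_overlap <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0L
  for (off in (-nb + 1L):(na - 1L)) {
    lo <- max(1L, 1L + off)
    hi <- min(na, nb + off)
    len <- hi - lo + 1L
    if (len <= best) next
    if (substr(a, lo, hi) == substr(b, lo - off, hi - off)) best <- len
  }
  best
}

## does k-mer k (either orientation, rc precomputed) shift-overlap s?
.overlaps <- function(k, k_rc, s, min_ov) {
  need <- min(min_ov, nchar(k), nchar(s))
  .max_overlap(s, k) >= need || .max_overlap(s, k_rc) >= need
}

## fraction of reads containing `motif` on either strand
.containment_frac <- function(seqs, motif) {
  hit <- grepl(motif, seqs, fixed = TRUE) |
    grepl(.revcomp_dna(motif), seqs, fixed = TRUE)
  c(n = sum(hit), frac = mean(hit))
}

#' Discover differentially enriched motifs between two read sets
#'
#' Counts, for each width, the number of reads containing each k-mer (on
#' either strand) in the WT and control sets, scores each k-mer by a
#' one-sided two-proportion test of the containment fractions, and greedily
#' merges shift-overlapping and reverse-complement k-mers into consensus
#' motifs. Within a cluster the consensus width is the largest width whose
#' read support stays within `support_tol` of the best member - for a
#' tandem repeat this stops exactly at the repeat-unit length, because
#' wrap-around k-mers longer than one unit are absent from single-unit
#' products. Because libraries are strand-randomized, a consensus and its
#' reverse complement are equivalent reports; the orientation with more raw
#' occurrences in the WT set is returned.
#'
#' @param wt_unmapped,ctrl_unmapped [read_set]s (or character vectors) of
#'   unmapped reads for the WT and control conditions; both must be
#'   nonempty.
#' @param widths Integer vector of k-mer widths to scan (widths exceeding
#'   the longest read are skipped with a warning).
#' @param top_n Number of consensus motifs to return.
#' @param min_overlap Minimum exact ungapped overlap for merging two k-mers.
#' @param support_tol Tolerated fractional loss of read support when
#'   growing the consensus width.
#' @param max_candidates Number of top-scoring k-mers entering clustering.
#' @return A data.frame of class `enriched_motifs` with columns `consensus`,
#'   `width`, `n_sites` (total WT hits of the consensus), `frac_wt`,
#'   `frac_ctrl` (per-read containment fractions, recomputed for the
#'   consensus itself), `p_value` and `log10_p`.
#' @export
discover_motifs <- function(wt_unmapped, ctrl_unmapped, widths = 6:12,
                            top_n = 5L, min_overlap = 5L,
                            support_tol = 0.05, max_candidates = 1000L) {
  wt <- toupper(.readset_seqs(wt_unmapped))
  ct <- toupper(.readset_seqs(ctrl_unmapped))
  if (!length(wt) || !length(ct))
    stop("both read sets must be nonempty", call. = FALSE)
  n1 <- length(wt); n2 <- length(ct)
  max_len <- max(nchar(wt))
  stats_list <- list()
  for (w in sort(unique(as.integer(widths)))) {
    if (w > max_len) {
      warning("width ", w, " exceeds the longest read; skipped")
      next
    }
    cw <- .kmer_containment(wt, w)
    if (!nrow(cw)) next
    cc <- .kmer_containment(ct, w)
    tab <- merge(cw, cc, by = "kmer", all.x = TRUE, suffixes = c("_wt", "_ctrl"))
    tab[is.na(tab$n_ctrl), "n_ctrl" := 0L]
    tab[, "width" := w]
    stats_list[[as.character(w)]] <- tab
  }
  empty <- data.frame(consensus = character(0), width = integer(0),
                      n_sites = integer(0), frac_wt = numeric(0),
                      frac_ctrl = numeric(0), p_value = numeric(0),
                      log10_p = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("enriched_motifs", "data.frame")
  if (!length(stats_list)) return(empty)
  tab <- data.table::rbindlist(stats_list)
  sc <- .two_prop_logp(tab$n_wt, n1, tab$n_ctrl, n2)
  tab[, "logp" := sc$logp]
  data.table::setorderv(tab, c("logp", "n_wt", "kmer"), c(1L, -1L, 1L))
  cand <- utils::head(tab, max_candidates)
  cand <- as.data.frame(cand)
  cand$rc <- .revcomp_dna(cand$kmer)

  out <- list()
  while (nrow(cand) && length(out) < top_n) {
    seed <- cand$kmer[1L]
    in_cluster <- mapply(.overlaps, cand$kmer, cand$rc,
                         MoreArgs = list(s = seed, min_ov = min_overlap))
    members <- cand[in_cluster, , drop = FALSE]
    ## consensus width: largest width whose support is within support_tol
    ## of the best-supported member
    sup <- tapply(members$n_wt, members$width, max)
    best_sup <- max(sup)
    ok_w <- as.integer(names(sup))[sup >= (1 - support_tol) * best_sup]
    w_star <- max(ok_w)
    mw <- members[members$width == w_star, , drop = FALSE]
    consensus <- mw$kmer[which.max(mw$n_wt)]
    ## absorb everything consistent with a tandem array of the consensus
    doubled <- strrep(consensus, ceiling(max(cand$width) / w_star) + 1L)
    in_tandem <- unique(unlist(lapply(unique(cand$width), function(w) {
      if (w > nchar(doubled)) return(character(0))
      substring(doubled, 1:(nchar(doubled) - w + 1L), w:nchar(doubled))
    })))
    absorbed <- in_cluster | cand$kmer %in% in_tandem | cand$rc %in% in_tandem
    cand <- cand[!absorbed, , drop = FALSE]
    ## orientation: report the strand with more raw WT occurrences
    rc <- .revcomp_dna(consensus)
    n_f <- sum(vapply(gregexpr(consensus, wt, fixed = TRUE), function(m)
      if (m[1] == -1L) 0L else length(m), integer(1)))
    n_r <- sum(vapply(gregexpr(rc, wt, fixed = TRUE), function(m)
      if (m[1] == -1L) 0L else length(m), integer(1)))
    if (n_r > n_f) consensus <- rc
    fr_wt <- .containment_frac(wt, consensus)
    fr_ct <- .containment_frac(ct, consensus)
    sc1 <- .two_prop_logp(fr_wt[["n"]], n1, fr_ct[["n"]], n2)
    sc_all <- .scan_all(wt, consensus)
    out[[length(out) + 1L]] <- data.frame(
      consensus = consensus, width = nchar(consensus),
      n_sites = sum(lengths(sc_all$hits)),
      frac_wt = fr_wt[["frac"]], frac_ctrl = fr_ct[["frac"]],
      p_value = exp(sc1$logp), log10_p = sc1$logp / log(10),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  class(res) <- c("enriched_motifs", "data.frame")
  res
}

#' @export
print.enriched_motifs <- function(x, ...) {
  cat("Differentially enriched motifs (", nrow(x), " consensus motif(s))\n",
      sep = "")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 4, ...)
  invisible(x)
}
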