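## Read-level analysis: partitioning against a reference, motif scanning,
## position graphs, repeat-run histograms, context logos, period estimation.

.readset_seqs <- function(readset) {
  if (inherits(readset, "read_set") || is.data.frame(readset))
    return(readset$sequence)
  if (is.character(readset)) return(readset)
  stop("expected a read_set, data.frame or character vector", call. = FALSE)
}

.readset_nref <- function(readset) {
  n <- attr(readset, "n_reference_mapping")
  if (is.null(n)) 0L else n
}

.readset_read_len <- function(readset) {
  rl <- attr(readset, "read_len")
  if (is.null(rl)) max(nchar(.readset_seqs(readset)), 1L) else rl
}

#' Partition reads into reference-mapping and unmapped sets
#'
#' A read maps iff it shares an exact contiguous substring of at least
#' `min_anchor` bases with the reference or its reverse complement (a
#' transparent anchor criterion standing in for a full aligner). Both
#' returned sets carry the mapped count as their `n_reference_mapping`, the
#' denominator for counts-per-million normalization.
#'
#' @param reads A [read_set].
#' @param reference Reference DNA string (length >= `min_anchor`).
#' @param min_anchor Anchor length in nt; values below 10 warn (spurious
#'   matches become likely).
#' @return A list with elements `mapped` and `unmapped`, both [read_set]s.
#' @export
partition_unmapped <- function(reads, reference, min_anchor = 30L) {
  stopifnot(inherits(reads, "read_set"))
  .assert_scalar_string(reference, "reference")
  reference <- toupper(reference)
  min_anchor <- as.integer(min_anchor)
  if (nchar(reference) < min_anchor)
    stop("reference shorter than min_anchor", call. = FALSE)
  if (min_anchor < 10L)
    warning("min_anchor < 10 nt: spurious matches are likely")
  k <- min_anchor
  refs <- c(reference, .revcomp_dna(reference))
  anchors <- unique(unlist(lapply(refs, function(r)
    substring(r, 1:(nchar(r) - k + 1L), k:nchar(r)))))
  seqs <- reads$sequence
  lens <- nchar(seqs)
  mapped <- logical(length(seqs))
  max_off <- max(lens) - k + 1L
  if (max_off >= 1L) {
    for (j in seq_len(max_off)) {
      idx <- which(!mapped & lens >= j + k - 1L)
      if (!length(idx)) break
      hit <- substr(seqs[idx], j, j + k - 1L) %in% anchors
      mapped[idx[hit]] <- TRUE
    }
  }
  n_map <- sum(mapped)
  mk <- function(sel) read_set(reads[sel, , drop = FALSE],
                               reference_id = attr(reads, "reference_id"),
                               n_reference_mapping = n_map,
                               read_len = attr(reads, "read_len"))
  list(mapped = mk(mapped), unmapped = mk(!mapped))
}

## non-overlapping greedy hit starts (1-based) of `motif` in each of `seqs`;
## exact matching (gregexpr) or Hamming-tolerant sliding scan
.hits_fixed <- function(seqs, motif, max_mismatch = 0L) {
  if (max_mismatch == 0L) {
    g <- gregexpr(motif, seqs, fixed = TRUE)
    return(lapply(g, function(m) if (m[1] == -1L) integer(0) else as.integer(m)))
  }
  w <- nchar(motif)
  mo <- strsplit(motif, "", fixed = TRUE)[[1]]
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < w) return(integer(0))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- integer(0)
    i <- 1L
    while (i <= n - w + 1L) {
      if (sum(ch[i:(i + w - 1L)] != mo) <= max_mismatch) {
        out <- c(out, i)
        i <- i + w
      } else i <- i + 1L
    }
    out
  })
}

## Scan all reads on both strands; choose, per read, the orientation with
## more hits (ties -> forward). Returns list(hits = list of 0-based starts,
## orientation = "+"/"-", oriented = read sequence in chosen orientation).
.scan_all <- function(seqs, motif, max_mismatch = 0L) {
  fwd <- .hits_fixed(seqs, motif, max_mismatch)
  rc <- .revcomp_dna(seqs)
  rev <- .hits_fixed(rc, motif, max_mismatch)
  use_rev <- lengths(rev) > lengths(fwd)
  hits <- fwd
  hits[use_rev] <- rev[use_rev]
  oriented <- seqs
  oriented[use_rev] <- rc[use_rev]
  list(hits = lapply(hits, function(h) h - 1L),
       orientation = ifelse(use_rev, "-", "+"),
       oriented = oriented)
}

#' Scan a read for non-overlapping motif hits
#'
#' Exact (or optionally Hamming-tolerant), non-overlapping, left-to-right
#' greedy matching. The read is scanned in both orientations and the
#' orientation with more hits is used (ties go to the forward strand);
#' positions are reported in the chosen orientation.
#'
#' @param read A DNA string.
#' @param motif A non-empty DNA motif.
#' @param max_mismatch Hamming tolerance per hit (default 0, exact).
#' @return Integer vector of 0-based start positions, with attribute
#'   `orientation` (`"+"` or `"-"`).
#' @examples
#' scan_hits(strrep("GAATCATTG", 3), "GAATCATTG")
#' @export
scan_hits <- function(read, motif, max_mismatch = 0L) {
  .assert_scalar_string(read, "read")
  .assert_scalar_string(motif, "motif")
  sc <- .scan_all(toupper(read), toupper(motif), as.integer(max_mismatch))
  structure(sc$hits[[1]], orientation = sc$orientation[1])
}

#' Motif position graph
#'
#' For each read, hit start coordinates are shifted so the read's first hit
#' sits at 0, then hit counts are summed position-wise over all reads across
#' the read length. Tandem-repeat cDNAs show up as combs at multiples of the
#' repeat period. Counts are also scaled as counts per million
#' reference-mapping reads when a positive denominator is available.
#'
#' @param readset A [read_set] (its `n_reference_mapping` supplies the CPM
#'   denominator) or character vector of reads.
#' @param motif DNA motif to scan for.
#' @param max_mismatch Hamming tolerance passed to the scanner.
#' @return Object of class `motif_position_graph`: list with `counts`
#'   (length `read_len`, index 0-based via `position`), `cpm` (NULL when the
#'   denominator is 0), `motif`, `n_reads_with_hit`, `n_reference_mapping`.
#' @export
position_graph <- function(readset, motif, max_mismatch = 0L) {
  .assert_scalar_string(motif, "motif")
  seqs <- .readset_seqs(readset)
  read_len <- .readset_read_len(readset)
  n_ref <- .readset_nref(readset)
  sc <- .scan_all(seqs, toupper(motif), as.integer(max_mismatch))
  counts <- integer(read_len)
  for (h in sc$hits) {
    if (!length(h)) next
    rel <- h - h[1]
    rel <- rel[rel < read_len]
    counts[rel + 1L] <- counts[rel + 1L] + 1L
  }
  cpm <- NULL
  if (n_ref > 0L) cpm <- counts * 1e6 / n_ref
  else message("n_reference_mapping is 0: cpm undefined, returning raw counts only")
  structure(list(position = seq_len(read_len) - 1L, counts = counts,
                 cpm = cpm, motif = toupper(motif),
                 n_reads_with_hit = counts[1L],
                 n_reference_mapping = n_ref),
            class = "motif_position_graph")
}

#' @export
print.motif_position_graph <- function(x, ...) {
  nz <- which(x$counts > 0L)
  cat("Motif position graph for '", x$motif, "': ", x$n_reads_with_hit,
      " read(s) with hits, ", length(nz), " nonzero position(s)\n", sep = "")
  if (length(nz)) {
    show <- utils::head(nz, 12L)
    cat("  positions:", paste(x$position[show], collapse = " "),
        if (length(nz) > 12L) "...", "\n")
    cat("  counts:   ", paste(x$counts[show], collapse = " "),
        if (length(nz) > 12L) "...", "\n")
  }
  invisible(x)
}

#' @export
plot.motif_position_graph <- function(x, use_cpm = !is.null(x$cpm), ...) {
  y <- if (use_cpm && !is.null(x$cpm)) x$cpm else x$counts
  ylab <- if (use_cpm && !is.null(x$cpm)) "counts per million mapping reads"
          else "hit count"
  graphics::plot(x$position, y, type = "h", lwd = 2,
                 xlab = "hit start relative to first hit (nt)", ylab = ylab,
                 main = paste0("Motif position graph: ", x$motif), ...)
  invisible(x)
}

## longest run of hits at exact unit spacing; hits are 0-based starts.
## max_skip interrupted units may be bridged (spacing a multiple of the
## motif length, up to (max_skip+1) units); run length counts hits.
.longest_run <- function(hits, unit, max_skip = 0L) {
  if (!length(hits)) return(0L)
  allowed <- unit * seq_len(max_skip + 1L)
  run <- 1L; best <- 1L
  if (length(hits) > 1L) {
    d <- diff(hits)
    for (g in d) {
      if (g %in% allowed) run <- run + 1L else run <- 1L
      if (run > best) best <- run
    }
  }
  best
}

#' Longest-repeat-run histogram
#'
#' Per read, the longest continuous stretch of motif hits at exact
#' motif-length spacing (a single hit counts as a run of 1; no hit as 0),
#' histogrammed over all reads. For a 150-nt read and a 9-nt motif the
#' attainable maximum is 16.
#'
#' @inheritParams position_graph
#' @param max_skip Number of interrupted units a run may bridge (default 0).
#' @return Object of class `repeat_run_histogram`: list with `bins` (named
#'   integer vector, run length -> read count), `median_run`, `runs`.
#' @export
repeat_run_histogram <- function(readset, motif, max_mismatch = 0L,
                                 max_skip = 0L) {
  .assert_scalar_string(motif, "motif")
  motif <- toupper(motif)
  seqs <- .readset_seqs(readset)
  sc <- .scan_all(seqs, motif, as.integer(max_mismatch))
  runs <- vapply(sc$hits, .longest_run, integer(1),
                 unit = nchar(motif), max_skip = as.integer(max_skip))
  tab <- table(factor(runs, levels = 0:max(runs, 0L)))
  bins <- as.integer(tab)
  names(bins) <- names(tab)
  structure(list(bins = bins, median_run = stats::median(runs), runs = runs,
                 motif = motif),
            class = "repeat_run_histogram")
}

#' @export
print.repeat_run_histogram <- function(x, ...) {
  cat("Repeat-run histogram for '", x$motif, "': ", sum(x$bins),
      " read(s), median longest run ", x$median_run, "\n", sep = "")
  nz <- x$bins[x$bins > 0L]
  print(nz)
  invisible(x)
}

#' @export
plot.repeat_run_histogram <- function(x, ...) {
  graphics::barplot(x$bins, xlab = "longest run of motif repeats per read",
                    ylab = "reads",
                    main = paste0("Longest repeat runs: ", x$motif), ...)
  invisible(x)
}

#' Count reads with at least k consecutive motif repeats (CPM-normalized)
#'
#' The number of reads whose longest run of motif hits at exact spacing is
#' at least `k`, scaled by 1e6 / `n_reference_mapping` (counts per million
#' reference-mapping reads).
#'
#' @inheritParams repeat_run_histogram
#' @param k Minimum run length (>= 1).
#' @return A single normalized count.
#' @export
count_min_repeat_reads <- function(readset, motif, k = 3L, max_mismatch = 0L,
                                   max_skip = 0L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  n_ref <- .readset_nref(readset)
  if (n_ref <= 0L)
    stop("n_reference_mapping must be > 0 for normalization", call. = FALSE)
  h <- repeat_run_histogram(readset, motif, max_mismatch = max_mismatch,
                            max_skip = max_skip)
  sum(h$runs >= k) * 1e6 / n_ref
}

#' Flanking-context logo (position frequency matrix) around motif hits
#'
#' For every motif hit (in each read's chosen orientation), the surrounding
#' window (motif plus `flank` nt on each side, truncated at read edges)
#' contributes to a position frequency matrix. For tandem-repeat cDNAs, the
#' flank columns reproduce the motif shifted by one period - the
#' direct-repeat signature.
#'
#' @inheritParams position_graph
#' @param flank Flank width in nt on each side of the motif.
#' @return Object of class `context_logo`: list with `pfm` (4 x
#'   (motif + 2*flank) matrix over rows A,C,G,T; column j sums to the number
#'   of sites covering that column), `motif`, `flank`, `n_sites`.
#' @export
context_logo <- function(readset, motif, flank = 9L, max_mismatch = 0L) {
  .assert_scalar_string(motif, "motif")
  motif <- toupper(motif)
  flank <- as.integer(flank)
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  seqs <- .readset_seqs(readset)
  sc <- .scan_all(seqs, motif, as.integer(max_mismatch))
  w <- nchar(motif)
  ncol_pfm <- w + 2L * flank
  bases <- c("A", "C", "G", "T")
  pfm <- matrix(0L, nrow = 4L, ncol = ncol_pfm,
                dimnames = list(bases, as.character(seq_len(ncol_pfm) -
                                                      flank - 1L)))
  n_sites <- 0L
  for (i in seq_along(seqs)) {
    h <- sc$hits[[i]]
    if (!length(h)) next
    s <- sc$oriented[i]
    n <- nchar(s)
    for (pos in h) {           # pos is 0-based hit start
      n_sites <- n_sites + 1L
      lo <- pos - flank        # 0-based window start
      from <- max(0L, lo)
      to <- min(n - 1L, pos + w + flank - 1L)
      chars <- strsplit(substr(s, from + 1L, to + 1L), "", fixed = TRUE)[[1]]
      cols <- (from - lo + 1L):(from - lo + length(chars))
      ridx <- match(chars, bases)
      keep <- !is.na(ridx)
      if (any(keep)) {
        idx <- cbind(ridx[keep], cols[keep])
        for (r in seq_len(nrow(idx)))
          pfm[idx[r, 1L], idx[r, 2L]] <- pfm[idx[r, 1L], idx[r, 2L]] + 1L
      }
    }
  }
  structure(list(pfm = pfm, motif = motif, flank = flank, n_sites = n_sites),
            class = "context_logo")
}

#' @export
print.context_logo <- function(x, ...) {
  cat("Context logo for '", x$motif, "' (+/-", x$flank, " nt flanks), ",
      x$n_sites, " site(s)\n", sep = "")
  cons <- rownames(x$pfm)[apply(x$pfm, 2L, which.max)]
  cat("  column consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' @export
plot.context_logo <- function(x, ...) {
  freq <- sweep(x$pfm, 2L, pmax(colSums(x$pfm), 1L), "/")
  graphics::matplot(as.integer(colnames(x$pfm)), t(freq), type = "l",
                    lty = 1, lwd = 2, col = c("forestgreen", "blue",
                                              "orange", "red"),
                    xlab = "position relative to motif start (nt)",
                    ylab = "base frequency",
                    main = paste0("Motif context: ", x$motif), ...)
  graphics::legend("topright", rownames(x$pfm), lty = 1, lwd = 2,
                   col = c("forestgreen", "blue", "orange", "red"),
                   bty = "n")
  invisible(x)
}

#' Estimate the dominant period of a motif position graph
#'
#' Returns the mode of the spacing distribution between successive nonzero
#' positions, each spacing weighted by the smaller of the two flanking
#' counts; ties are broken toward the smaller period.
#'
#' @param graph A [position_graph] result.
#' @return The dominant period (integer, nt).
#' @export
estimate_period <- function(graph) {
  stopifnot(inherits(graph, "motif_position_graph"))
  nz <- which(graph$counts > 0L)
  if (length(nz) < 2L)
    stop("period undefined: fewer than 2 nonzero positions", call. = FALSE)
  pos <- graph$position[nz]
  cnt <- graph$counts[nz]
  spacing <- diff(pos)
  weight <- pmin(cnt[-length(cnt)], cnt[-1L])
  agg <- tapply(weight, spacing, sum)
  cand <- as.integer(names(agg)[agg == max(agg)])
  min(cand)
}
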