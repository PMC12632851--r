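#' Base-pairing rules governing cDNA realignment
#'
#' After each completed repeat, the nascent cDNA dissociates and must
#' re-anneal to the template before the next extension cycle. These rules
#' encode the position-specific stringency of that annealing, counted as
#' depth from the primer 3' end (depth 1 = 3'-terminal base):
#' any mismatch within `strict_positions` aborts a candidate site; a
#' purine:purine mismatch (sterically clashing) aborts within
#' `purine_purine_block_depth`; from `free_depth` onward any mismatch is
#' tolerated. `p_success_by_matchlen` maps the contiguous 3'-terminal
#' Watson-Crick match length to the probability that annealing supports
#' another extension cycle (scores below the smallest key never succeed;
#' scores above the largest key use the largest).
#'
#' @param strict_positions Depths requiring exact Watson-Crick pairing.
#' @param purine_purine_block_depth Depth within which purine:purine
#'   mismatches abort (pyrimidine:pyrimidine is tolerated there).
#' @param free_depth Depth from which any mismatch is tolerated.
#' @param p_success_by_matchlen Named numeric vector mapping contiguous
#'   3'-terminal match length to realignment success probability.
#' @return An object of class `realign_rules`.
#' @export
realign_rules <- function(strict_positions = 2L,
                          purine_purine_block_depth = 3L,
                          free_depth = 4L,
                          p_success_by_matchlen = c("2" = 0.05, "3" = 0.5,
                                                    "4" = 0.95)) {
  strict_positions <- as.integer(strict_positions)
  purine_purine_block_depth <- as.integer(purine_purine_block_depth)
  free_depth <- as.integer(free_depth)
  if (!(strict_positions <= purine_purine_block_depth &&
        purine_purine_block_depth <= free_depth))
    stop("need strict_positions <= purine_purine_block_depth <= free_depth",
         call. = FALSE)
  p <- p_success_by_matchlen
  if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p)))) ||
      any(p < 0) || any(p > 1))
    stop("p_success_by_matchlen must be a named vector of probabilities",
         call. = FALSE)
  p <- p[order(as.integer(names(p)))]
  structure(list(strict_positions = strict_positions,
                 purine_purine_block_depth = purine_purine_block_depth,
                 free_depth = free_depth,
                 p_success_by_matchlen = p),
            class = "realign_rules")
}

#' Simulation configuration for repeat-addition and read generation
#'
#' @param p_continue Probability of attempting a further cycle after each
#'   completed repeat (geometric cycle-count law).
#' @param max_cycles Hard cap on the number of repeat units per product.
#' @param realign_rules A [realign_rules] object.
#' @param template_len_midpoint Template (A+B) length in nt at which the
#'   realignment-success decay reaches one half; encodes the loss of
#'   efficient template resetting for long templates.
#' @param template_len_scale Width (nt) of the sigmoid decay.
#' @param seq_error_rate Per-base substitution probability applied to reads.
#' @param read_len Read length in nt.
#' @param background_fraction Fraction of reads drawn from the reference.
#' @param seed Optional integer seed; when non-NULL, [generate_dataset] and
#'   [simulate_product] seed the RNG on entry so runs are reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p_continue = 0.98, max_cycles = 500L,
                       realign_rules = repeatweaver::realign_rules(),
                       template_len_midpoint = 14,
                       template_len_scale = 2,
                       seq_error_rate = 0.001, read_len = 150L,
                       background_fraction = 0.7, seed = NULL) {
  stopifnot(p_continue >= 0, p_continue <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            background_fraction >= 0, background_fraction <= 1,
            max_cycles >= 1L, read_len >= 1L,
            inherits(realign_rules, "realign_rules"),
            template_len_scale > 0)
  structure(list(p_continue = p_continue, max_cycles = as.integer(max_cycles),
                 realign_rules = realign_rules,
                 template_len_midpoint = template_len_midpoint,
                 template_len_scale = template_len_scale,
                 seq_error_rate = seq_error_rate,
                 read_len = as.integer(read_len),
                 background_fraction = background_fraction,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "sim_config")
}

## sigmoid decay of realignment success with template (A+B) length
.reset_decay <- function(tpl_len, config) {
  1 / (1 + exp((tpl_len - config$template_len_midpoint) /
                 config$template_len_scale))
}

## success probability for a contiguous 3'-terminal match of length `score`
.p_success <- function(score, rules) {
  keys <- as.integer(names(rules$p_success_by_matchlen))
  if (score < keys[1]) return(0)
  i <- findInterval(score, keys)
  unname(rules$p_success_by_matchlen[i])
}

## template RNA base paired by each primer DNA base (Watson-Crick)
.PAIR_OF_RNA <- c(A = "T", C = "G", G = "C", U = "A")
.PURINES_DNA <- c("A", "G")
.PURINES_RNA <- c("A", "G")

## Evaluate candidate annealing sites for a given primer 3' tail.
## seq_ch: template as a character vector; sites: template positions where
## the primer 3'-terminal base would pair. Returns data.frame(site, score)
## of sites that survive the abort rules, with score = contiguous
## 3'-terminal Watson-Crick match length.
.eval_sites <- function(seq_ch, sites, tail_ch, rules) {
  L <- length(seq_ch)
  plen <- length(tail_ch)
  keep <- integer(0); score <- integer(0)
  for (p in sites) {
    dmax <- min(plen, L - p + 1L)   # deepest depth with both bases present
    match_at <- function(d) d <= dmax &&
      .PAIR_OF_RNA[[seq_ch[p + d - 1L]]] == tail_ch[plen - d + 1L]
    ## abort zone: mismatches at depths 1 .. free_depth-1 can kill the site
    ok <- TRUE
    for (d in seq_len(rules$free_depth - 1L)) {
      if (match_at(d)) next
      if (d <= rules$strict_positions) { ok <- FALSE; break }
      if (d <= rules$purine_purine_block_depth && d <= dmax &&
          tail_ch[plen - d + 1L] %in% .PURINES_DNA &&
          seq_ch[p + d - 1L] %in% .PURINES_RNA) { ok <- FALSE; break }
    }
    if (!ok) next
    m <- 0L
    while (m < dmax && match_at(m + 1L)) m <- m + 1L
    keep <- c(keep, p); score <- c(score, m)
  }
  data.frame(site = keep, score = score)
}

#' Simulate one protein-primed tandem-repeat cDNA product
#'
#' Mechanistic model of telomerase-like repeat addition: cycle 1 reverse
#' transcribes the template A+B from the 3' end of B to the 5' end of A,
#' yielding one repeat unit; each further cycle requires (i) a continuation
#' draw against `p_continue`, (ii) a candidate annealing site between the
#' start of B and the end of A' whose pairing with the primer 3' tail
#' satisfies the [realign_rules], and (iii) a success draw with probability
#' `p_success_by_matchlen[score] * decay(template length)`. The
#' highest-scoring site is chosen (ties: closest to the canonical A', then a
#' seeded random draw). Extension then copies the template from one base
#' 5' of the site down to the 5' template boundary (the start of A), so
#' realignment at a non-canonical (cryptic) site yields an aberrant-length
#' unit. A and A' need not be identical on the supplied template: mutational
#' series are simulated by running a fixed pattern geometry on a perturbed
#' template, and realignment failure then emerges from the pairing rules.
#'
#' @param template An [ncrna_template].
#' @param pattern Pattern geometry (row of [find_aba_patterns] output or a
#'   list with `a_start`, `a_len`, `b_len`).
#' @param config A [sim_config]. When `config$seed` is non-NULL the RNG is
#'   seeded on entry; otherwise the current RNG stream is used.
#' @return An object of class `sim_product`: list with `sequence` (DNA,
#'   5'->3'), `n_repeats`, `realign_sites` (template positions used),
#'   `protein_primed_5prime` (always TRUE; records the covalent 5'
#'   protein-DNA linkage of protein-primed initiation).
#' @examples
#' tpl <- ncrna_template("eco3", "CAAUGAUUCCAAU", loop_interval = c(1, 13))
#' pat <- find_aba_patterns(tpl)[1, ]
#' set.seed(1)
#' simulate_product(tpl, pat, sim_config(p_continue = 0))
#' @export
simulate_product <- function(template, pattern, config = sim_config()) {
  stopifnot(inherits(template, "ncrna_template"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- .check_pattern_bounds(.as_pattern(pattern), template)
  rules <- config$realign_rules
  seq <- template$sequence
  L <- nchar(seq)
  seq_ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc_full <- .rna_to_cdna(seq)
  ## cDNA copy of template positions from..to (5'->3' of the cDNA)
  cdna_of <- function(from, to) substr(rc_full, L - to + 1L, L - from + 1L)
  tpl_len <- p$a_len + p$b_len
  decay <- .reset_decay(tpl_len, config)
  sites_all <- (p$a_start + p$a_len):(p$aprime_start + p$a_len - 1L)
  sites_all <- sites_all[sites_all <= L]
  tail_needed <- min(2L * tpl_len, 2L * p$a_len + p$b_len + 4L)

  cdna <- cdna_of(p$a_start, p$aprime_start - 1L)
  n_repeats <- 1L
  realign_sites <- integer(0)
  memo <- new.env(parent = emptyenv())

  while (n_repeats < config$max_cycles) {
    if (stats::runif(1) >= config$p_continue) break
    tail <- substr(cdna, max(1L, nchar(cdna) - tail_needed + 1L), nchar(cdna))
    cand <- get0(tail, envir = memo, inherits = FALSE)
    if (is.null(cand)) {
      cand <- .eval_sites(seq_ch, sites_all,
                          strsplit(tail, "", fixed = TRUE)[[1]], rules)
      assign(tail, cand, envir = memo)
    }
    if (!nrow(cand)) break
    best_score <- max(cand$score)
    top <- cand[cand$score == best_score, , drop = FALSE]
    dist <- abs(top$site - p$aprime_start)
    top <- top[dist == min(dist), , drop = FALSE]
    site <- if (nrow(top) > 1L) top$site[sample.int(nrow(top), 1L)] else
      top$site[1L]
    if (stats::runif(1) >= .p_success(best_score, rules) * decay) break
    if (site > p$a_start) cdna <- paste0(cdna, cdna_of(p$a_start, site - 1L))
    n_repeats <- n_repeats + 1L
    realign_sites <- c(realign_sites, site)
  }
  structure(list(sequence = cdna, n_repeats = n_repeats,
                 realign_sites = realign_sites,
                 protein_primed_5prime = TRUE),
            class = "sim_product")
}

#' @export
print.sim_product <- function(x, ...) {
  cat("Simulated cDNA product: ", x$n_repeats, " repeat unit(s), ",
      nchar(x$sequence), " nt", if (x$protein_primed_5prime)
        " (protein-primed 5' end)", "\n", sep = "")
  cat("  ", if (nchar(x$sequence) > 60L)
    paste0(substr(x$sequence, 1L, 57L), "...") else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Construct a labeled sequencing read set
#'
#' @param reads data.frame with columns `id`, `sequence`, `condition`
#'   (`"WT"` or `"RT_dead"`) and `truth` (`"repeat_product"` or
#'   `"background"`).
#' @param reference_id Identifier of the reference the background reads were
#'   drawn from / mapped against.
#' @param n_reference_mapping Number of reference-mapping reads, the
#'   denominator of all counts-per-million normalizations.
#' @param read_len Nominal read length (reads may be shorter, never longer).
#' @return An object of class `read_set` (a data.frame with attributes).
#' @export
read_set <- function(reads, reference_id = "reference",
                     n_reference_mapping = 0L, read_len = NULL) {
  stopifnot(is.data.frame(reads),
            all(c("id", "sequence", "condition", "truth") %in% names(reads)))
  read_len <- as.integer(read_len %||% max(nchar(reads$sequence), 0L))
  if (nrow(reads) && any(nchar(reads$sequence) > read_len))
    stop("read longer than read_len", call. = FALSE)
  if (n_reference_mapping < 0L)
    stop("n_reference_mapping must be >= 0", call. = FALSE)
  structure(as.data.frame(reads, stringsAsFactors = FALSE),
            reference_id = reference_id,
            n_reference_mapping = as.integer(n_reference_mapping),
            read_len = read_len,
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set: ", nrow(x), " read(s), read_len ", attr(x, "read_len"),
      ", reference '", attr(x, "reference_id"), "' (",
      attr(x, "n_reference_mapping"), " reference-mapping)\n", sep = "")
  if (nrow(x)) {
    tb <- table(x$condition, x$truth)
    print(tb)
  }
  invisible(x)
}

## random window of a sequence (current RNG); whole sequence if shorter
.random_window <- function(s, width) {
  n <- nchar(s)
  if (n <= width) return(s)
  start <- sample.int(n - width + 1L, 1L)
  substr(s, start, start + width - 1L)
}

## apply per-base substitution errors to a character vector of reads
.apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Generate a synthetic miniprep-seq read set
#'
#' Emulates the sequencing layer over simulated repeat-addition products.
#' In the WT condition, a `background_fraction` Bernoulli draw sends each
#' read to the reference (a uniform random window, either strand) or to an
#' independently simulated cDNA product (a random window of the product, or
#' the whole product when it is shorter than the read length). The RT-dead
#' condition contains background reads only. Reads are emitted in the cDNA
#' orientation with 50/50 strand randomization, then subjected to
#' substitution errors at `seq_error_rate`. Ground-truth origin labels are
#' recorded, and `n_reference_mapping` is set to the background read count.
#'
#' @param template An [ncrna_template] (required for WT).
#' @param pattern Pattern geometry (see [simulate_product]); may be NULL for
#'   the RT-dead condition.
#' @param reference Reference DNA string (length >= `read_len`).
#' @param config A [sim_config]; `config$seed`, when non-NULL, makes the
#'   whole read set reproducible.
#' @param n_reads Number of reads to generate.
#' @param condition `"WT"` or `"RT_dead"`.
#' @return A [read_set].
#' @export
generate_dataset <- function(template = NULL, pattern = NULL, reference,
                             config = sim_config(), n_reads,
                             condition = c("WT", "RT_dead")) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "sim_config"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L)
    stop("n_reads must be a positive integer", call. = FALSE)
  .assert_scalar_string(reference, "reference")
  reference <- toupper(reference)
  if (nchar(reference) < config$read_len)
    stop("reference shorter than read_len", call. = FALSE)
  if (condition == "WT" && config$background_fraction < 1 &&
      (is.null(pattern) || is.null(template)))
    stop("WT condition with repeat reads requires template and pattern",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  ## per-product config must not re-seed inside the loop
  prod_config <- config; prod_config$seed <- NULL

  is_bg <- if (condition == "RT_dead") rep(TRUE, n_reads) else
    stats::runif(n_reads) < config$background_fraction
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (is_bg[i]) {
      seqs[i] <- .random_window(reference, config$read_len)
    } else {
      prod <- simulate_product(template, pattern, prod_config)
      seqs[i] <- .random_window(prod$sequence, config$read_len)
    }
  }
  flip <- stats::runif(n_reads) < 0.5
  if (any(flip)) seqs[flip] <- .revcomp_dna(seqs[flip])
  seqs <- .apply_errors(seqs, config$seq_error_rate)
  reads <- data.frame(
    id = sprintf("%s_read_%06d", condition, seq_len(n_reads)),
    sequence = seqs,
    condition = condition,
    truth = ifelse(is_bg, "background", "repeat_product"),
    stringsAsFactors = FALSE)
  read_set(reads, reference_id = "reference",
           n_reference_mapping = sum(is_bg), read_len = config$read_len)
}
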