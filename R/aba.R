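#' Search parameters for A-B-A' pattern detection
#'
#' The template architecture of repeat-synthesizing DRT10/telomerase-like
#' ncRNAs is a direct repeat A-B-A': the template proper is A+B, and A' is a
#' downstream copy of A that mediates realignment of the nascent cDNA. These
#' parameters bound the search.
#'
#' @param min_a,max_a Minimum/maximum length of the repeated segment A (nt).
#'   Characterized systems range from 2 nt (Eco1/Eco2-like) to 4 nt
#'   (Eco3-like), so the default window 2-10 brackets them.
#' @param min_motif,max_motif Bounds on the encoded repeat-unit (A+B) length.
#' @param restrict_to_loop Restrict the search to the template loop (the
#'   user-supplied `loop_interval`, or the longest unpaired run of a supplied
#'   dot-bracket structure).
#' @return An object of class `aba_search_params`.
#' @export
aba_search_params <- function(min_a = 2L, max_a = 10L,
                              min_motif = 4L, max_motif = 30L,
                              restrict_to_loop = TRUE) {
  min_a <- as.integer(min_a); max_a <- as.integer(max_a)
  min_motif <- as.integer(min_motif); max_motif <- as.integer(max_motif)
  if (min_a < 1L || min_a > max_a)
    stop("need 1 <= min_a <= max_a", call. = FALSE)
  if (min_motif > max_motif)
    stop("need min_motif <= max_motif", call. = FALSE)
  structure(list(min_a = min_a, max_a = max_a, min_motif = min_motif,
                 max_motif = max_motif,
                 restrict_to_loop = isTRUE(restrict_to_loop)),
            class = "aba_search_params")
}

## empty result table, shared by find_aba_patterns and its callers
.empty_aba <- function(template_id) {
  out <- data.frame(a_start = integer(0), a_len = integer(0),
                    b_len = integer(0), aprime_start = integer(0),
                    motif_dna = character(0), stringsAsFactors = FALSE)
  attr(out, "template_id") <- template_id
  class(out) <- c("aba_patterns", "data.frame")
  out
}

#' Find A-B-A' direct-repeat patterns in an ncRNA template
#'
#' Enumerates every pattern in which a segment A (length `min_a..max_a`) is
#' repeated exactly at A', separated by a spacer B (length >= 0), with the
#' repeat-unit (A+B) length inside `min_motif..max_motif` and the whole
#' pattern inside the search interval. A must be maximal: a pattern whose A
#' could be extended one base leftward at both sites (stealing the last base
#' of B) while staying within bounds is suppressed as redundant.
#'
#' Patterns are ranked by `a_len` descending (longer A-A' homology drives
#' realignment), then `b_len` ascending, then `a_start` ascending.
#'
#' @param template An [ncrna_template].
#' @param params An [aba_search_params] object.
#' @return A data.frame of class `aba_patterns` with columns `a_start`,
#'   `a_len`, `b_len`, `aprime_start` (all 1-based), and `motif_dna`, the
#'   encoded cDNA repeat unit (reverse complement of A+B, written 5'->3').
#' @examples
#' tpl <- ncrna_template("eco3", "CAAUGAUUCCAAU")
#' find_aba_patterns(tpl, aba_search_params(restrict_to_loop = FALSE))
#' @export
find_aba_patterns <- function(template, params = aba_search_params()) {
  stopifnot(inherits(template, "ncrna_template"),
            inherits(params, "aba_search_params"))
  seq <- template$sequence
  iv <- .search_interval(template, params$restrict_to_loop)
  s <- iv[1]; e <- iv[2]
  rows <- vector("list", 0L)
  for (a_len in seq(params$max_a, params$min_a)) {
    d_lo <- max(a_len, params$min_motif)          # motif length = a_len + b_len
    d_hi <- params$max_motif
    if (d_lo > d_hi) next
    for (d in d_lo:d_hi) {
      ## A at i..i+a_len-1, A' at i+d..i+d+a_len-1, both inside [s, e]
      i_max <- e - d - a_len + 1L
      if (i_max < s) next
      i <- s:i_max
      hit <- substring(seq, i, i + a_len - 1L) ==
             substring(seq, i + d, i + d + a_len - 1L)
      if (!any(hit)) next
      i <- i[hit]
      b_len <- d - a_len
      ## leftward maximality: extendable iff one more matching base exists to
      ## the left of both A and A', and the grown A still fits the bounds
      ext <- (i - 1L >= s) & (b_len >= 1L) & (a_len + 1L <= params$max_a) &
        (substring(seq, i - 1L, i - 1L) == substring(seq, i + d - 1L, i + d - 1L))
      i <- i[!ext]
      if (length(i))
        rows[[length(rows) + 1L]] <-
          data.frame(a_start = i, a_len = a_len, b_len = b_len,
                     aprime_start = i + d, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_aba(template$id))
  out <- do.call(rbind, rows)
  out <- out[order(-out$a_len, out$b_len, out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out$motif_dna <- .rna_to_cdna(substring(seq, out$a_start,
                                          out$aprime_start - 1L))
  attr(out, "template_id") <- template$id
  class(out) <- c("aba_patterns", "data.frame")
  out
}

#' @export
print.aba_patterns <- function(x, ...) {
  cat("A-B-A' patterns for template '",
      attr(x, "template_id") %||% "?", "': ", nrow(x), " pattern(s)\n",
      sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L), ...)
  if (nrow(x) > 20L) cat("... and", nrow(x) - 20L, "more\n")
  invisible(x)
}

## Coerce a one-row aba_patterns table / list / first row of a table into a
## plain pattern list with integer coordinates.
.as_pattern <- function(pattern) {
  if (inherits(pattern, "aba_patterns") || is.data.frame(pattern)) {
    if (nrow(pattern) < 1L) stop("empty pattern table", call. = FALSE)
    pattern <- as.list(pattern[1L, , drop = FALSE])
  }
  need <- c("a_start", "a_len", "b_len")
  if (!all(need %in% names(pattern)))
    stop("pattern must carry a_start, a_len and b_len", call. = FALSE)
  p <- lapply(pattern[need], as.integer)
  p$aprime_start <- p$a_start + p$a_len + p$b_len
  p
}

## bounds check of a pattern against a template (identity of A and A' is NOT
## required here: mutational simulations run patterns on perturbed templates).
## Motif prediction only needs the template A+B inside the sequence;
## simulation additionally needs the A' annealing segment.
.check_pattern_bounds <- function(p, template, need_aprime = TRUE) {
  n <- nchar(template$sequence)
  last <- if (need_aprime) p$aprime_start + p$a_len - 1L else
    p$aprime_start - 1L
  if (p$a_start < 1L || p$a_len < 1L || p$b_len < 0L || last > n)
    stop("pattern out of bounds for template '", template$id, "' (", n,
         " nt)", call. = FALSE)
  invisible(p)
}

#' Predict the cDNA repeat motif encoded by an A-B-A' pattern
#'
#' The repeat unit synthesized per cycle is the reverse complement of the
#' RNA template segment A+B, read 5'->3' of the cDNA (U->A, A->T, C->G,
#' G->C).
#'
#' @param pattern A row of [find_aba_patterns] output, or a list with
#'   `a_start`, `a_len`, `b_len`.
#' @param template The [ncrna_template] the pattern lives on.
#' @return A DNA string (the repeat unit).
#' @examples
#' tpl <- ncrna_template("eco3", "CAAUGAUUCCAAU")
#' p <- find_aba_patterns(tpl, aba_search_params(restrict_to_loop = FALSE))
#' predict_repeat_motif(p[1, ], tpl)
#' @export
predict_repeat_motif <- function(pattern, template) {
  stopifnot(inherits(template, "ncrna_template"))
  p <- .check_pattern_bounds(.as_pattern(pattern), template,
                             need_aprime = FALSE)
  .rna_to_cdna(substr(template$sequence, p$a_start, p$aprime_start - 1L))
}

#' Design an ncRNA template segment encoding an arbitrary repeat motif
#'
#' Constructs the minimal A-B-A' RNA segment whose iterated reverse
#' transcription yields tandem repeats of `motif_dna`: the reverse-complement
#' RNA of the motif (the template A+B) followed by a copy of its first
#' `a_len` bases (the A' realignment segment).
#'
#' @param motif_dna Desired DNA repeat unit (5'->3').
#' @param a_len Length of the A/A' realignment segment; must be shorter than
#'   the motif.
#' @return An RNA string of length `nchar(motif_dna) + a_len`.
#' @examples
#' design_template("TTAGGG", 3)   # human telomeric repeat
#' @export
design_template <- function(motif_dna, a_len) {
  .assert_scalar_string(motif_dna, "motif_dna")
  motif_dna <- toupper(motif_dna)
  if (!.is_dna(motif_dna))
    stop("motif_dna contains non-DNA characters", call. = FALSE)
  a_len <- as.integer(a_len)
  if (a_len < 1L || a_len >= nchar(motif_dna))
    stop("need 1 <= a_len < nchar(motif_dna)", call. = FALSE)
  ab <- .dna_to_template_rna(motif_dna)
  paste0(ab, substr(ab, 1L, a_len))
}

#' Batch A-B-A' prevalence over a collection of ncRNA templates
#'
#' Runs [find_aba_patterns] over a collection and tabulates, per ncRNA,
#' whether any pattern is identifiable, the top-ranked pattern, and the
#' midpoint of its A-B-A' span (one midpoint per ncRNA, for non-redundant
#' positional summaries). The aggregate fraction of ncRNAs with a pattern is
#' attached as attribute `fraction` (NA for an empty collection, not zero).
#'
#' @param templates List of [ncrna_template] objects.
#' @param params An [aba_search_params] object.
#' @return A data.frame with one row per template: `id`, `has_pattern`,
#'   `a_start`, `a_len`, `b_len`, `aprime_start`, `motif_dna`,
#'   `motif_midpoint`; attribute `fraction` holds the aggregate prevalence.
#' @export
batch_aba_prevalence <- function(templates, params = aba_search_params()) {
  stopifnot(is.list(templates))
  rows <- lapply(templates, function(tpl) {
    stopifnot(inherits(tpl, "ncrna_template"))
    pats <- find_aba_patterns(tpl, params)
    if (nrow(pats)) {
      top <- pats[1L, ]
      data.frame(id = tpl$id, has_pattern = TRUE,
                 a_start = top$a_start, a_len = top$a_len, b_len = top$b_len,
                 aprime_start = top$aprime_start, motif_dna = top$motif_dna,
                 motif_midpoint =
                   (top$a_start + top$aprime_start + top$a_len - 1L) / 2,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = tpl$id, has_pattern = FALSE, a_start = NA_integer_,
                 a_len = NA_integer_, b_len = NA_integer_,
                 aprime_start = NA_integer_, motif_dna = NA_character_,
                 motif_midpoint = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), has_pattern = logical(0),
               a_start = integer(0), a_len = integer(0), b_len = integer(0),
               aprime_start = integer(0), motif_dna = character(0),
               motif_midpoint = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction") <-
    if (nrow(out)) mean(out$has_pattern) else NA_real_
  out
}
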