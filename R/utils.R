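## Shared sequence utilities. Sequences are plain uppercase character scalars
## or vectors; RNA over {A,C,G,U}, DNA over {A,C,G,T}.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom Biostrings DNAStringSet reverseComplement
.revcomp_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rna_to_dna <- function(x) chartr("U", "T", toupper(x))
.dna_to_rna <- function(x) chartr("T", "U", toupper(x))

## reverse-complement an RNA template into the cDNA (DNA) it encodes
.rna_to_cdna <- function(x) .revcomp_dna(.rna_to_dna(x))

## reverse-complement a DNA motif into the RNA that would template it
.dna_to_template_rna <- function(x) .dna_to_rna(.revcomp_dna(x))

.is_rna <- function(x) !grepl("[^ACGU]", x)
.is_dna <- function(x) !grepl("[^ACGT]", x)

.assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
}

## balanced round-bracket check for dot-bracket strings
.brackets_balanced <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    return(FALSE)
  depth <- cumsum((ch == "(") - (ch == ")"))
  all(depth >= 0L) && depth[length(depth)] == 0L
}

## longest run of unpaired ('.') positions in a dot-bracket string,
## returned as c(start, end) 1-based inclusive, or NULL if none
.max_unpaired_run <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  r <- rle(ch == ".")
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  best <- i[which.max(r$lengths[i])]
  c(starts[best], ends[best])
}

## random DNA string(s); uses the current RNG stream
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a random DNA reference sequence
#'
#' Draws a uniform-composition DNA string from the current RNG stream. Used
#' as the plasmid/reference stand-in when simulating sequencing read sets.
#'
#' @param length Reference length in nt.
#' @return A single DNA string.
#' @examples
#' set.seed(1)
#' nchar(random_reference(300))
#' @export
random_reference <- function(length = 3000L) {
  stopifnot(length >= 1L)
  .random_dna(1L, as.integer(length))
}
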