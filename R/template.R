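#' Construct an ncRNA template object
#'
#' Represents a noncoding RNA carrying a reverse-transcription template, with
#' an optional dot-bracket secondary structure and an optional template-loop
#' interval. Coordinates are 1-based inclusive on the RNA sequence.
#'
#' @param id Sequence identifier.
#' @param sequence RNA string over `A,C,G,U`. DNA input (`T`) is normalized to
#'   `U`; lowercase is upper-cased.
#' @param structure Optional dot-bracket string of the same length with
#'   balanced brackets.
#' @param loop_interval Optional integer vector `c(start, end)` (1-based,
#'   inclusive) delimiting the template loop. When absent but a structure is
#'   supplied, the loop is taken as the longest unpaired run.
#' @return An object of class `ncrna_template`: a list with elements `id`,
#'   `sequence`, `structure`, `loop_interval`.
#' @examples
#' tpl <- ncrna_template("eco3", "CAAUGAUUCCAAU")
#' tpl
#' @export
ncrna_template <- function(id, sequence, structure = NULL, loop_interval = NULL) {
  .assert_scalar_string(id, "id")
  .assert_scalar_string(sequence, "sequence")
  sequence <- .dna_to_rna(sequence)
  if (!.is_rna(sequence))
    stop("template '", id, "': sequence contains non-RNA characters",
         call. = FALSE)
  n <- nchar(sequence)
  if (!is.null(structure)) {
    .assert_scalar_string(structure, "structure")
    if (nchar(structure) != n)
      stop("template '", id, "': structure length (", nchar(structure),
           ") differs from sequence length (", n, ")", call. = FALSE)
    if (!.brackets_balanced(structure))
      stop("template '", id, "': structure has unbalanced brackets",
           call. = FALSE)
  }
  if (!is.null(loop_interval)) {
    loop_interval <- as.integer(loop_interval)
    if (length(loop_interval) != 2L || anyNA(loop_interval) ||
        loop_interval[1] < 1L || loop_interval[2] > n ||
        loop_interval[1] > loop_interval[2])
      stop("template '", id, "': loop_interval must lie within [1, ", n, "]",
           call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, structure = structure,
                 loop_interval = loop_interval),
            class = "ncrna_template")
}

#' @export
print.ncrna_template <- function(x, ...) {
  cat("ncRNA template '", x$id, "' (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  ", x$sequence, "\n", sep = "")
  if (!is.null(x$structure)) cat("  ", x$structure, "\n", sep = "")
  if (!is.null(x$loop_interval))
    cat("  template loop: ", x$loop_interval[1], "-", x$loop_interval[2],
        "\n", sep = "")
  invisible(x)
}

## Resolve the search interval for pattern detection: the user-supplied loop,
## else the longest unpaired run of the structure, else (restricted search
## only) an error; unrestricted search uses the whole sequence.
.search_interval <- function(template, restrict) {
  n <- nchar(template$sequence)
  if (!restrict) return(c(1L, n))
  if (!is.null(template$loop_interval)) return(template$loop_interval)
  if (!is.null(template$structure)) {
    run <- .max_unpaired_run(template$structure)
    if (!is.null(run)) return(run)
  }
  stop("template '", template$id, "': restrict_to_loop = TRUE but no ",
       "loop_interval (and no structure to derive one from); supply a loop ",
       "or set restrict_to_loop = FALSE", call. = FALSE)
}

#' Read ncRNA templates from FASTA (with optional sidecar annotations)
#'
#' Reads a FASTA file of ncRNA sequences (RNA or DNA alphabet; `T` is
#' normalized to `U`) and, optionally, a tab-separated sidecar with per-record
#' loop intervals and dot-bracket structures.
#'
#' @param fasta_path Path to the FASTA file.
#' @param sidecar_path Optional path to a TSV with columns `id`, and any of
#'   `loop_start`, `loop_end`, `dot_bracket`.
#' @return A list of [ncrna_template] objects, named by id.
#' @export
read_templates <- function(fasta_path, sidecar_path = NULL) {
  fa <- read_fasta(fasta_path, molecule = "RNA")
  side <- if (!is.null(sidecar_path)) read_dot_bracket_tsv(sidecar_path) else NULL
  out <- lapply(seq_len(nrow(fa)), function(i) {
    id <- fa$id[i]
    loop <- NULL; db <- NULL
    if (!is.null(side) && id %in% side$id) {
      row <- side[side$id == id, , drop = FALSE][1, ]
      if (!is.null(row$loop_start) && !is.na(row$loop_start))
        loop <- c(row$loop_start, row$loop_end)
      if (!is.null(row$dot_bracket) && !is.na(row$dot_bracket))
        db <- row$dot_bracket
    }
    ncrna_template(id, fa$sequence[i], structure = db, loop_interval = loop)
  })
  names(out) <- fa$id
  out
}
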