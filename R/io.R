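## File I/O (FASTA/FASTQ/TSV/JSON), configuration and the end-to-end
## pipeline runner.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param molecule `"as_is"` keeps the alphabet (upper-cased); `"DNA"`
#'   normalizes `U -> T`; `"RNA"` normalizes `T -> U`. Normalization is
#'   applied exactly once, at ingest.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, molecule = c("as_is", "DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  if (molecule == "DNA") seqs <- chartr("U", "T", seqs)
  if (molecule == "RNA") seqs <- chartr("T", "U", seqs)
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param x data.frame with `id`, `sequence`, or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- data.frame(id = names(x), sequence = unname(x),
                                       stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sequence") %in% names(x)))
  lines <- character(2L * nrow(x))
  lines[c(TRUE, FALSE)] <- paste0(">", x$id)
  lines[c(FALSE, TRUE)] <- x$sequence
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line-record FASTQ. Malformed records raise an error naming the
#' file, the record index and the offending line.
#'
#' @param path Path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4", call. = FALSE)
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("malformed FASTQ '", path, "', record ", bad[1],
         ": header line does not start with '@': ", hd[bad[1]],
         call. = FALSE)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ '", path, "', record ", bad[1],
         ": separator line does not start with '+': ", pl[bad[1]],
         call. = FALSE)
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("malformed FASTQ '", path, "', record ", bad[1],
         ": sequence and quality lengths differ: ", sq[bad[1]],
         call. = FALSE)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hd)),
             sequence = toupper(sq), quality = qu, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param x A [read_set] or data.frame with `id`, `sequence` and optionally
#'   `quality` (defaults to a constant placeholder quality `I`).
#' @param path Output path.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  qual <- if ("quality" %in% names(x)) x$quality else
    strrep("I", nchar(x$sequence))
  lines <- character(4L * nrow(x))
  lines[seq(1L, by = 4L, length.out = nrow(x))] <- paste0("@", x$id)
  lines[seq(2L, by = 4L, length.out = nrow(x))] <- x$sequence
  lines[seq(3L, by = 4L, length.out = nrow(x))] <- "+"
  lines[seq(4L, by = 4L, length.out = nrow(x))] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a dot-bracket / loop-interval sidecar TSV
#'
#' Expected columns: `id`, and any of `loop_start`, `loop_end`,
#' `dot_bracket`. Unbalanced brackets or inconsistent intervals raise an
#' error naming the record.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_dot_bracket_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df))
    stop("sidecar '", path, "' lacks an 'id' column", call. = FALSE)
  if ("dot_bracket" %in% names(df)) {
    for (i in seq_len(nrow(df))) {
      db <- df$dot_bracket[i]
      if (!is.na(db) && nzchar(db) && !.brackets_balanced(db))
        stop("sidecar '", path, "', record ", i, " (id '", df$id[i],
             "'): unbalanced dot-bracket string", call. = FALSE)
    }
  }
  if (all(c("loop_start", "loop_end") %in% names(df))) {
    bad <- which(!is.na(df$loop_start) &
                   (df$loop_start < 1L | df$loop_start > df$loop_end))
    if (length(bad))
      stop("sidecar '", path, "', record ", bad[1], " (id '", df$id[bad[1]],
           "'): invalid loop interval", call. = FALSE)
  }
  df
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an R object as JSON
#' @param x Object.
#' @param path Output path.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Demo pipeline configuration (Eco3-like repeat system)
#'
#' A self-contained configuration reproducing the canonical analysis on
#' synthetic data: the 13-nt Eco3-like template loop `CAAUGAUUCCAAU`
#' (A = CAAU, B = GAUUC, A' = CAAU; encoded repeat GAATCATTG), a random
#' 3-kb reference, paired WT and RT-dead read sets, and the full
#' partition / discover / quantify analysis.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory for artifacts.
#' @param n_reads Reads per condition.
#' @param reference_length Length of the generated reference.
#' @return A configuration list for [run_pipeline].
#' @export
demo_config <- function(seed = 7L, out_dir = tempfile("repeatweaver_run_"),
                        n_reads = 2000L, reference_length = 3000L) {
  list(seed = as.integer(seed),
       out_dir = out_dir,
       template = list(id = "Eco3_like_template_loop",
                       sequence = "CAAUGAUUCCAAU",
                       loop_interval = c(1L, 13L)),
       reference_length = as.integer(reference_length),
       n_reads = as.integer(n_reads),
       aba = list(min_a = 2L, max_a = 10L, min_motif = 4L, max_motif = 30L,
                  restrict_to_loop = TRUE),
       sim = list(p_continue = 0.98, max_cycles = 500L,
                  template_len_midpoint = 14, template_len_scale = 2,
                  seq_error_rate = 0.001, read_len = 150L,
                  background_fraction = 0.7),
       pipeline = list(min_anchor = 30L, widths = 6:12, top_n = 5L,
                       min_repeat_k = 3L, flank = 9L,
                       min_ctrl_unmapped = 100L))
}

.config_from <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  config
}

#' Run the full synthetic-data analysis pipeline
#'
#' simulate -> partition -> discover -> quantify, writing all artifacts
#' (FASTQ read sets plus truth tables, pattern and motif tables, position
#' graph, run histogram, context PFM) and a JSON run report under
#' `config$out_dir`. Identical configuration and seed yield byte-identical
#' artifacts. When the control condition has fewer unmapped reads than
#' `pipeline$min_ctrl_unmapped` (synthetic backgrounds map almost
#' completely), the full control read set serves as the background
#' comparator for motif discovery.
#'
#' @param config Configuration list (see [demo_config]) or path to a JSON
#'   file with the same structure. A seed is mandatory because simulation
#'   is stochastic.
#' @return The run report (list of parameters, counts and summary
#'   statistics), invisibly written to `report.json`.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- .config_from(config)
  if (is.null(config$seed))
    stop("configuration error: seed is mandatory (stochastic stages enabled)",
         call. = FALSE)
  out_dir <- config$out_dir %||% tempfile("repeatweaver_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pl <- config$pipeline
  set.seed(config$seed)

  ## --- template & pattern -------------------------------------------------
  tpl_cfg <- config$template
  tpl <- ncrna_template(tpl_cfg$id %||% "template", tpl_cfg$sequence,
                        structure = tpl_cfg$structure,
                        loop_interval = tpl_cfg$loop_interval)
  aba <- do.call(aba_search_params, config$aba %||% list())
  pats <- find_aba_patterns(tpl, aba)
  if (!nrow(pats))
    stop("stage aba-find failed: no A-B-A' pattern in template '", tpl$id,
         "'", call. = FALSE)
  pat <- pats[1L, ]
  motif_true <- pat$motif_dna
  write_tsv(as.data.frame(pats), file.path(out_dir, "aba_patterns.tsv"))

  ## --- simulate -----------------------------------------------------------
  sim_args <- config$sim %||% list()
  sim_args$realign_rules <- do.call(realign_rules,
                                    config$realign_rules %||% list())
  cfg <- do.call(sim_config, sim_args)
  reference <- random_reference(config$reference_length %||% 3000L)
  n_reads <- config$n_reads %||% 2000L
  wt <- generate_dataset(tpl, pat, reference, cfg, n_reads, "WT")
  ctrl <- generate_dataset(NULL, NULL, reference, cfg, n_reads, "RT_dead")
  write_fastq(wt, file.path(out_dir, "wt.fastq"))
  write_fastq(ctrl, file.path(out_dir, "rt_dead.fastq"))
  write_tsv(as.data.frame(wt)[, c("id", "condition", "truth")],
            file.path(out_dir, "wt_truth.tsv"))
  write_tsv(as.data.frame(ctrl)[, c("id", "condition", "truth")],
            file.path(out_dir, "rt_dead_truth.tsv"))
  write_fasta(stats::setNames(reference, "reference"),
              file.path(out_dir, "reference.fasta"))

  ## --- partition ----------------------------------------------------------
  min_anchor <- pl$min_anchor %||% 30L
  part_wt <- partition_unmapped(wt, reference, min_anchor)
  part_ct <- partition_unmapped(ctrl, reference, min_anchor)
  ctrl_cmp <- part_ct$unmapped
  ctrl_fallback <- nrow(ctrl_cmp) < (pl$min_ctrl_unmapped %||% 100L)
  if (ctrl_fallback) ctrl_cmp <- ctrl

  ## --- discover -----------------------------------------------------------
  motifs <- discover_motifs(part_wt$unmapped, ctrl_cmp,
                            widths = pl$widths %||% 6:12,
                            top_n = pl$top_n %||% 5L)
  if (!nrow(motifs))
    stop("stage discover failed: no motif recovered", call. = FALSE)
  write_tsv(as.data.frame(motifs), file.path(out_dir, "motifs.tsv"))
  top <- motifs$consensus[1L]

  ## --- quantify -----------------------------------------------------------
  graph <- position_graph(part_wt$unmapped, top)
  hist <- repeat_run_histogram(part_wt$unmapped, top)
  logo <- context_logo(part_wt$unmapped, top, flank = pl$flank %||% 9L)
  period <- estimate_period(graph)
  cpm3 <- count_min_repeat_reads(part_wt$unmapped, top,
                                 k = pl$min_repeat_k %||% 3L)
  write_tsv(data.frame(position = graph$position, counts = graph$counts,
                       cpm = graph$cpm %||% NA_real_),
            file.path(out_dir, "position_graph.tsv"))
  write_tsv(data.frame(run_length = as.integer(names(hist$bins)),
                       reads = hist$bins),
            file.path(out_dir, "repeat_run_histogram.tsv"))
  utils::write.table(logo$pfm, file.path(out_dir, "context_pfm.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  report <- list(
    package_version = as.character(utils::packageVersion("repeatweaver")),
    seed = config$seed,
    parameters = config[c("template", "reference_length", "n_reads", "aba",
                          "sim", "pipeline")],
    template_pattern = as.list(as.data.frame(pat)),
    true_motif = motif_true,
    reads = list(
      wt_total = nrow(wt), wt_mapped = nrow(part_wt$mapped),
      wt_unmapped = nrow(part_wt$unmapped),
      ctrl_total = nrow(ctrl), ctrl_mapped = nrow(part_ct$mapped),
      ctrl_unmapped = nrow(part_ct$unmapped),
      ctrl_comparator_fallback = ctrl_fallback,
      dropped = 0L),
    discovery = list(top_motif = top, top_width = motifs$width[1L],
                     frac_wt = motifs$frac_wt[1L],
                     frac_ctrl = motifs$frac_ctrl[1L],
                     p_value = motifs$p_value[1L]),
    quantification = list(period = period,
                          median_longest_run = hist$median_run,
                          reads_ge_k_per_million = cpm3,
                          n_reference_mapping = attr(part_wt$unmapped,
                                                     "n_reference_mapping")))
  write_json(report, file.path(out_dir, "report.json"))
  class(report) <- "rw_report"
  invisible(report)
}

#' @export
print.rw_report <- function(x, ...) {
  cat("repeatweaver run (seed ", x$seed, ")\n", sep = "")
  cat("  true repeat motif:      ", x$true_motif, "\n", sep = "")
  cat("  discovered top motif:   ", x$discovery$top_motif, " (width ",
      x$discovery$top_width, ")\n", sep = "")
  cat("  position-graph period:  ", x$quantification$period, " nt\n", sep = "")
  cat("  median longest run:     ", x$quantification$median_longest_run,
      "\n", sep = "")
  cat("  reads with >=3 repeats: ",
      round(x$quantification$reads_ge_k_per_million, 1),
      " per million mapping reads\n", sep = "")
  invisible(x)
}
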