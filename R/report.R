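# End-to-end pipeline driver and the candidate-table exports.
#
# The TSV mirrors the classic result-table layout: one row per candidate
# with position, protospacer, PAM, GC/Tm/TTTT annotations and the
# "20mer+PAM" / "12mer+PAM" / "8mer+PAM" hit-count columns.  The JSON
# export carries the same fields plus run metadata, and round-trips
# byte-identically.

REPORT_COLUMNS <- c("position", "strand", "target_seq", "pam_seq",
                    "gc_percent", "tm_celsius", "has_tttt", "hits_full",
                    "hits_seed12", "hits_seed8", "highlighted",
                    "zero_hit_warning")

#' Run the full guide-design pipeline
#'
#' Enumerates PAM-adjacent candidates in the query, builds (or reuses) the
#' genome k-mer+PAM index, fills hit counts and highlighting, and assembles
#' a reproducible report.
#'
#' @param query Path to a single-record query FASTA, or a
#'   `genome_collection` with one record.
#' @param genome Path to a (multi-record) genome FASTA, or a
#'   `genome_collection`.
#' @param params A `design_params`.
#' @param budget An `alignment_budget`, echoed into the metadata for
#'   reproducibility of follow-up detail searches.
#' @param index Optional pre-built `kmer_pam_index` for `genome`.
#' @param timestamp Include a wall-clock timestamp in the metadata
#'   (set FALSE for byte-identical reruns).
#' @param verbose Log progress per stage via `message()`.
#' @return A list of class `design_report`: `query_id`, `query_length`,
#'   `params`, `budget`, `genome_id`, `candidates`, `version`, `timestamp`.
#' @export
run_design <- function(query, genome, params = design_params(),
                       budget = alignment_budget(), index = NULL,
                       timestamp = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  if (is.character(query) && !inherits(query, "genome_collection") &&
      length(query) == 1L && file.exists(query)) {
    say("reading query: ", query)
    query <- read_fasta(query)
  }
  if (is.character(genome) && !inherits(genome, "genome_collection") &&
      length(genome) == 1L && file.exists(genome)) {
    say("reading genome: ", genome)
    genome <- read_fasta(genome)
  }
  say("stage pamscan: enumerating candidates")
  cand <- enumerate_candidates(query, params)
  say("  ", nrow(cand), " candidates")
  if (is.null(index)) {
    say("stage kmerindex: building index over ", total_length(genome), " bases")
    index <- build_index(genome, params)
  }
  say("stage kmerindex: annotating hit counts")
  cand <- annotate_and_highlight(cand, index)
  say("stage report: assembling")
  structure(list(
    query_id = attr(cand, "query_id"),
    query_length = attr(cand, "query_length"),
    params = params,
    budget = budget,
    genome_id = index$genome_id,
    candidates = cand,
    version = as.character(utils::packageVersion("grnadesign")),
    timestamp = if (timestamp) format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z") else NULL
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("design_report: query", x$query_id, "(", x$query_length, "bp ) |",
      nrow(x$candidates), "candidates |", sum(x$candidates$highlighted),
      "highlighted\n")
  invisible(x)
}

fmt_num1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
fmt_int <- function(x) ifelse(is.na(x), "", as.character(x))
fmt_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))

#' Export a design report as tab-delimited text
#'
#' Header plus one row per candidate.  Position is "start..end" (1-based
#' inclusive, plus strand, spanning protospacer+PAM); GC and Tm carry one
#' decimal; missing annotations serialize as the empty string.
#'
#' @param report A `design_report`.
#' @param path Optional output path; if NULL the text is returned.
#' @return The TSV text (invisibly if written to `path`).
#' @export
export_tsv <- function(report, path = NULL) {
  cd <- report$candidates
  rows <- if (nrow(cd) == 0L) character(0) else paste(
    paste0(cd$start, "..", cd$end), cd$strand, cd$target_seq, cd$pam_seq,
    fmt_num1(cd$gc_percent), fmt_num1(cd$tm_celsius), fmt_bool(cd$has_tttt),
    fmt_int(cd$hits_full), fmt_int(cd$hits_seed12), fmt_int(cd$hits_seed8),
    fmt_bool(cd$highlighted), fmt_bool(cd$zero_hit_warning),
    sep = "\t")
  txt <- paste0(paste(c(paste(REPORT_COLUMNS, collapse = "\t"), rows),
                      collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # LF endings on every platform
    writeLines(txt, con, sep = "")
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Parse TSV text produced by [export_tsv()]
#' @param txt TSV text or a path to a TSV file.
#' @return Data frame with start, end and the report columns, typed.
#' @export
parse_tsv <- function(txt) {
  if (length(txt) == 1L && !grepl("\n", txt) && file.exists(txt)) {
    txt <- paste0(paste(readLines(txt), collapse = "\n"), "\n")
  }
  df <- utils::read.table(text = txt, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  pos <- strsplit(df$position, "..", fixed = TRUE)
  out <- data.frame(
    start = vapply(pos, function(p) as.integer(p[1]), integer(1)),
    end = vapply(pos, function(p) as.integer(p[2]), integer(1)),
    strand = df$strand, target_seq = df$target_seq, pam_seq = df$pam_seq,
    gc_percent = as.numeric(ifelse(df$gc_percent == "", NA, df$gc_percent)),
    tm_celsius = as.numeric(ifelse(df$tm_celsius == "", NA, df$tm_celsius)),
    has_tttt = as.logical(df$has_tttt),
    hits_full = as.integer(ifelse(df$hits_full == "", NA, df$hits_full)),
    hits_seed12 = as.integer(ifelse(df$hits_seed12 == "", NA, df$hits_seed12)),
    hits_seed8 = as.integer(ifelse(df$hits_seed8 == "", NA, df$hits_seed8)),
    highlighted = as.logical(df$highlighted),
    zero_hit_warning = as.logical(df$zero_hit_warning),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L) out <- out[0L, , drop = FALSE]
  out
}

report_metadata_list <- function(report) {
  p <- report$params; b <- report$budget
  list(
    query_id = report$query_id,
    query_length = report$query_length,
    genome_id = report$genome_id,
    params = list(pam_pattern = p$pam_pattern, target_len = p$target_len,
                  seed_lens = as.list(p$seed_lens),
                  max_query_len = p$max_query_len,
                  tm_na_mM = p$tm_na_mM, tm_oligo_uM = p$tm_oligo_uM,
                  tm_method = p$tm_method),
    budget = list(max_mismatches = b$max_mismatches, max_gaps = b$max_gaps,
                  require_pam = b$require_pam),
    version = report$version,
    timestamp = report$timestamp
  )
}

#' Export a design report as JSON
#'
#' One document: a metadata object (query, parameter echo, genome checksum,
#' tool version, optional timestamp) and a candidate array carrying the same
#' field names as the TSV.  Key order is fixed, so identical reports give
#' byte-identical JSON; missing values serialize as null.
#'
#' @param report A `design_report`.
#' @param path Optional output path; if NULL the JSON text is returned.
#' @return The JSON text (invisibly if written to `path`).
#' @export
export_json <- function(report, path = NULL) {
  cd <- report$candidates
  cands <- lapply(seq_len(nrow(cd)), function(i) {
    list(position = paste0(cd$start[i], "..", cd$end[i]),
         strand = cd$strand[i], target_seq = cd$target_seq[i],
         pam_seq = cd$pam_seq[i], gc_percent = cd$gc_percent[i],
         tm_celsius = cd$tm_celsius[i], has_tttt = cd$has_tttt[i],
         hits_full = cd$hits_full[i], hits_seed12 = cd$hits_seed12[i],
         hits_seed8 = cd$hits_seed8[i], highlighted = cd$highlighted[i],
         zero_hit_warning = cd$zero_hit_warning[i])
  })
  doc <- list(metadata = report_metadata_list(report), candidates = cands)
  txt <- paste0(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                 null = "null", na = "null", pretty = TRUE),
                "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeLines(txt, con, sep = "")
    close(con)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a design report from its JSON export
#'
#' Inverse of [export_json()]: `export_json(import_json(txt))` is
#' byte-identical to `txt`.
#'
#' @param txt JSON text or a path to a JSON file.
#' @return A `design_report` (candidates carry the exported fields).
#' @export
import_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  md <- doc$metadata
  params <- design_params(pam_pattern = md$params$pam_pattern,
                          target_len = md$params$target_len,
                          seed_lens = unlist(md$params$seed_lens),
                          max_query_len = md$params$max_query_len,
                          tm_na_mM = md$params$tm_na_mM,
                          tm_oligo_uM = md$params$tm_oligo_uM)
  budget <- alignment_budget(md$budget$max_mismatches, md$budget$max_gaps,
                             md$budget$require_pam)
  g <- function(v) if (is.null(v)) NA else v
  cands <- doc$candidates
  pos <- lapply(cands, function(cc) strsplit(cc$position, "..", fixed = TRUE)[[1]])
  cd <- data.frame(
    start = vapply(pos, function(p) as.integer(p[1]), integer(1)),
    end = vapply(pos, function(p) as.integer(p[2]), integer(1)),
    strand = vapply(cands, function(cc) cc$strand, character(1)),
    target_seq = vapply(cands, function(cc) cc$target_seq, character(1)),
    pam_seq = vapply(cands, function(cc) cc$pam_seq, character(1)),
    gc_percent = vapply(cands, function(cc) as.numeric(g(cc$gc_percent)), numeric(1)),
    tm_celsius = vapply(cands, function(cc) as.numeric(g(cc$tm_celsius)), numeric(1)),
    has_tttt = vapply(cands, function(cc) as.logical(g(cc$has_tttt)), logical(1)),
    hits_full = vapply(cands, function(cc) as.integer(g(cc$hits_full)), integer(1)),
    hits_seed12 = vapply(cands, function(cc) as.integer(g(cc$hits_seed12)), integer(1)),
    hits_seed8 = vapply(cands, function(cc) as.integer(g(cc$hits_seed8)), integer(1)),
    highlighted = vapply(cands, function(cc) as.logical(g(cc$highlighted)), logical(1)),
    zero_hit_warning = vapply(cands, function(cc) as.logical(g(cc$zero_hit_warning)),
                              logical(1)),
    stringsAsFactors = FALSE)
  attr(cd, "params") <- params
  attr(cd, "query_id") <- md$query_id
  attr(cd, "query_length") <- md$query_length
  attr(cd, "genome_id") <- md$genome_id
  class(cd) <- c("target_candidates", "data.frame")
  structure(list(query_id = md$query_id, query_length = md$query_length,
                 params = params, budget = budget, genome_id = md$genome_id,
                 candidates = cd, version = md$version,
                 timestamp = if (is.null(md$timestamp)) NULL else md$timestamp),
            class = "design_report")
}
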