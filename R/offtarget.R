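# Mismatch- and gap-tolerant search of a protospacer against a genome.
#
# Two stages: a Myers bit-parallel semi-global scan (the query, <= 31 nt,
# fits one machine word; R integers are 32-bit) screens every end position
# whose edit distance to some query alignment is within the total budget;
# a small gap-layered dynamic program then verifies each candidate locus,
# splits the edit tally into substitutions vs indels, and producs the
# alignment strings for the mismatch/gap visualization.

#' Mismatch/gap budget for approximate off-target search
#'
#' @param max_mismatches Maximum substitutions, default 3.
#' @param max_gaps Maximum indels (insertions + deletions combined),
#'   default 1.
#' @param require_pam Drop hits whose genomic PAM fails the pattern,
#'   default FALSE: the detail view lists sites by sequence similarity and
#'   only reports the PAM; set TRUE for Cas9-realistic filtering.
#' @return A list of class `alignment_budget`.
#' @export
alignment_budget <- function(max_mismatches = 3L, max_gaps = 1L,
                             require_pam = FALSE) {
  max_mismatches <- as.integer(max_mismatches)
  max_gaps <- as.integer(max_gaps)
  stopifnot(max_mismatches >= 0L, max_gaps >= 0L, is.logical(require_pam))
  structure(list(max_mismatches = max_mismatches, max_gaps = max_gaps,
                 require_pam = require_pam),
            class = "alignment_budget")
}

# Myers (1999) bit-parallel approximate matching, semi-global (free start
# and end in the subject).  Returns end positions j where the best
# alignment of the full query ending at j has edit distance <= max_dist.
myers_ends <- function(query, subject, max_dist) {
  m <- nchar(query)
  stopifnot(m >= 1L, m <= 31L)
  n <- nchar(subject)
  if (n == 0L) return(integer(0))
  qc <- strsplit(query, "")[[1]]
  peq <- integer(256)
  for (i in seq_len(m)) {
    b <- utf8ToInt(qc[i])
    peq[b + 1L] <- bitwOr(peq[b + 1L], bitwShiftL(1L, i - 1L))
  }
  sc <- utf8ToInt(subject)
  mask <- bitwShiftL(1L, m) - 1L
  top <- bitwShiftL(1L, m - 1L)
  pv <- mask; mv <- 0L; score <- m
  ends <- integer(0)
  for (j in seq_len(n)) {
    eq <- peq[sc[j] + 1L]
    xv <- bitwOr(eq, mv)
    xh <- bitwOr(bitwXor(bitwAnd(eq, pv) + pv, pv), eq)
    ph <- bitwAnd(bitwOr(mv, bitwNot(bitwOr(xh, pv))), mask)
    mh <- bitwAnd(pv, xh)
    if (bitwAnd(ph, top) != 0L) score <- score + 1L
    else if (bitwAnd(mh, top) != 0L) score <- score - 1L
    # shifting in 0 keeps the subject start free (semi-global)
    ph <- bitwAnd(bitwShiftL(ph, 1L), mask)
    mh <- bitwAnd(bitwShiftL(mh, 1L), mask)
    pv <- bitwAnd(bitwOr(mh, bitwNot(bitwOr(xv, ph))), mask)
    mv <- bitwAnd(ph, xv)
    if (score <= max_dist) ends <- c(ends, j)
  }
  ends
}

# Gap-layered global alignment of query against a window, minimizing
# (n_gap, n_mismatch) lexicographically.  Gaps cost one unit of the gap
# budget; substitutions one mismatch.  Returns NULL if infeasible within
# (max_gaps, max_mismatches), else list(n_gap, n_mismatch, aligned_query,
# aligned_subject, marker_line).
align_window <- function(query, window, max_mismatches, max_gaps) {
  q <- strsplit(query, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(q); L <- length(w)
  if (abs(L - m) > max_gaps) return(NULL)
  INF <- .Machine$integer.max %/% 4L
  G <- max_gaps + 1L
  # dp[[g+1]][i+1, j+1]: min mismatches using <= g gaps
  dp <- vector("list", G)
  for (gi in seq_len(G)) {
    g <- gi - 1L
    M <- matrix(INF, m + 1L, L + 1L)
    M[1L, 1L] <- 0L
    if (g >= 1L) {
      M[1L, seq_len(min(g, L)) + 1L] <- 0L
      M[seq_len(min(g, m)) + 1L, 1L] <- 0L
    }
    for (i in seq_len(m)) {
      for (j in seq_len(L)) {
        best <- M[i, j] + (q[i] != w[j])
        if (g >= 1L) {
          prev <- dp[[gi - 1L]]
          if (prev[i, j + 1L] < best) best <- prev[i, j + 1L]  # gap in subject
          if (prev[i + 1L, j] < best) best <- prev[i + 1L, j]  # gap in query
        }
        if (best < M[i + 1L, j + 1L]) M[i + 1L, j + 1L] <- best
      }
    }
    dp[[gi]] <- M
  }
  gstar <- NA_integer_
  for (gi in seq_len(G)) {
    if (dp[[gi]][m + 1L, L + 1L] <= max_mismatches) { gstar <- gi - 1L; break }
  }
  if (is.na(gstar)) return(NULL)
  mm <- dp[[gstar + 1L]][m + 1L, L + 1L]
  # traceback from (gstar, m, L)
  aq <- character(0); as_ <- character(0); mk <- character(0)
  g <- gstar; i <- m; j <- L
  while (i > 0L || j > 0L) {
    cur <- dp[[g + 1L]][i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        dp[[g + 1L]][i, j] + (q[i] != w[j]) == cur) {
      aq <- c(q[i], aq); as_ <- c(w[j], as_)
      mk <- c(if (q[i] == w[j]) "|" else "X", mk)
      i <- i - 1L; j <- j - 1L
    } else if (g > 0L && i > 0L && dp[[g]][i, j + 1L] == cur) {
      aq <- c(q[i], aq); as_ <- c("-", as_); mk <- c(" ", mk)
      i <- i - 1L; g <- g - 1L
    } else if (g > 0L && j > 0L && dp[[g]][i + 1L, j] == cur) {
      aq <- c("-", aq); as_ <- c(w[j], as_); mk <- c(" ", mk)
      j <- j - 1L; g <- g - 1L
    } else {
      stop("traceback failed (internal error)")  # nocov
    }
  }
  list(n_gap = gstar, n_mismatch = as.integer(mm),
       aligned_query = paste(aq, collapse = ""),
       aligned_subject = paste(as_, collapse = ""),
       marker_line = paste(mk, collapse = ""))
}

# Collapse hits whose subject spans on the same record and strand overlap
# by >= 50% (of the shorter span) to the best-scoring one: fewest gaps,
# then fewest mismatches, then leftmost.
dedup_hits <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(df$n_gap, df$n_mismatch, df$start, df$end)
  kept <- df[0L, , drop = FALSE]
  for (i in ord) {
    h <- df[i, , drop = FALSE]
    clash <- FALSE
    if (nrow(kept) > 0L) {
      same <- kept$record_id == h$record_id & kept$strand == h$strand
      if (any(same)) {
        ov <- pmax(0L, pmin(kept$end[same], h$end) -
                     pmax(kept$start[same], h$start) + 1L)
        shorter <- pmin(kept$end[same] - kept$start[same] + 1L,
                        h$end - h$start + 1L)
        clash <- any(ov >= 0.5 * shorter)
      }
    }
    if (!clash) kept <- rbind(kept, h)
  }
  kept[order(kept$record_id, kept$start, kept$strand), , drop = FALSE]
}

#' Search a genome for approximate matches to a protospacer
#'
#' Finds every locus on either strand alignable to the query with at most
#' `max_mismatches` substitutions and `max_gaps` indels under unit costs.
#' Among overlapping alignments at one locus the one minimizing
#' (n_gap, n_mismatch) lexicographically (then leftmost) is reported.
#' Coordinates are 1-based inclusive on the record's plus strand; alignment
#' strings are in protospacer-strand orientation.  The marker line writes
#' "|" for a match, "X" for a mismatch and " " for a gap column.  The PAM
#' observed immediately 3' of the matched span (protospacer strand) is
#' reported for every hit; with `require_pam` it is enforced.
#'
#' @param query Protospacer string over {A,C,G,T} (2-31 nt).
#' @param genome A `genome_collection`.
#' @param budget An `alignment_budget`.
#' @param pam_pattern IUPAC PAM pattern used to judge `pam_ok`.
#' @return Data frame of hits: record_id, start, end, strand, n_mismatch,
#'   n_gap, pam_at_site, pam_ok, aligned_query, marker_line,
#'   aligned_subject; sorted by record then start.
#' @export
search_approximate <- function(query, genome, budget = alignment_budget(),
                               pam_pattern = "NGG") {
  stopifnot(inherits(budget, "alignment_budget"))
  query <- normalize_sequence(query, "query")
  if (grepl("N", query)) stop("query may not contain N", call. = FALSE)
  m <- nchar(query)
  if (m < 2L || m > 31L) {
    stop("query must be 2-31 bases, got ", m, call. = FALSE)
  }
  total <- budget$max_mismatches + budget$max_gaps
  plen <- nchar(pam_pattern)
  pam_codes <- strsplit(toupper(pam_pattern), "")[[1]]
  lens <- (m - budget$max_gaps):(m + budget$max_gaps)

  rows <- list()
  for (rid in names(genome)) {
    rec <- unclass(genome)[[rid]]
    L <- nchar(rec)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") rec else reverse_complement(rec)
      ends <- myers_ends(query, subject, total)
      seen <- character(0)
      for (e in ends) {
        for (len in lens) {
          s <- e - len + 1L
          if (s < 1L) next
          key <- paste0(s, ":", e)
          if (key %in% seen) next
          seen <- c(seen, key)
          al <- align_window(query, substr(subject, s, e),
                             budget$max_mismatches, budget$max_gaps)
          if (is.null(al)) next
          pam_raw <- if (e + plen <= nchar(subject)) {
            substr(subject, e + 1L, e + plen)
          } else {
            substr(subject, e + 1L, nchar(subject))
          }
          pam_ok <- nchar(pam_raw) == plen &&
            !grepl("N", pam_raw) &&
            all(iupac_matches(strsplit(pam_raw, "")[[1]], pam_codes))
          # map scanned-strand span to plus-strand coordinates
          if (strand == "+") { start <- s; end <- e }
          else { start <- L - e + 1L; end <- L - s + 1L }
          rows[[length(rows) + 1L]] <- data.frame(
            record_id = rid, start = start, end = end, strand = strand,
            n_mismatch = al$n_mismatch, n_gap = al$n_gap,
            pam_at_site = pam_raw, pam_ok = pam_ok,
            aligned_query = al$aligned_query, marker_line = al$marker_line,
            aligned_subject = al$aligned_subject, stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), n_gap = integer(0),
                      pam_at_site = character(0), pam_ok = logical(0),
                      aligned_query = character(0), marker_line = character(0),
                      aligned_subject = character(0), stringsAsFactors = FALSE)
  df <- if (length(rows)) do.call(rbind, rows) else empty
  df <- dedup_hits(df)
  if (budget$require_pam) df <- df[df$pam_ok, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Cross-check exact counting against zero-budget approximate search
#'
#' The number of hits from [search_approximate()] with a zero mismatch/gap
#' budget and the PAM required must equal the "20 mer+PAM" exact count from
#' the k-mer index.  A cheap end-to-end consistency test of both engines.
#'
#' @param query Protospacer string of length target_len.
#' @param genome A `genome_collection`.
#' @param params A `design_params`.
#' @param index Optional pre-built `kmer_pam_index` for the same genome.
#' @return TRUE iff the two counts agree.
#' @export
count_consistency_check <- function(query, genome, params = design_params(),
                                    index = NULL) {
  if (is.null(index)) index <- build_index(genome, params)
  hits <- search_approximate(query, genome,
                             alignment_budget(0L, 0L, require_pam = TRUE),
                             pam_pattern = params$pam_pattern)
  nrow(hits) == unname(lookup_hits(index, query)["full"])
}

#' Write off-target hits as TSV
#' @param hits Data frame from [search_approximate()].
#' @param path Optional output path; if NULL the TSV text is returned.
#' @return The TSV text (invisibly if written to `path`).
#' @export
offtargets_tsv <- function(hits, path = NULL) {
  cols <- c("record_id", "start", "end", "strand", "n_mismatch", "n_gap",
            "pam_at_site", "pam_ok", "aligned_query", "marker_line",
            "aligned_subject")
  txt <- paste(c(paste(cols, collapse = "\t"),
                 vapply(seq_len(nrow(hits)), function(i) {
                   paste(vapply(cols, function(cl) as.character(hits[[cl]][i]),
                                character(1)), collapse = "\t")
                 }, character(1))),
               collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' Write off-target hits as BED6 for genome-browser overlay
#' @param hits Data frame from [search_approximate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
offtargets_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$record_id,
                    start = hits$start - 1L,      # BED is 0-based half-open
                    end = hits$end,
                    name = sprintf("mm%d_gap%d", hits$n_mismatch, hits$n_gap),
                    score = 0L,
                    strand = hits$strand,
                    stringsAsFactors = FALSE)
  write_bed(bed, path)
}
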