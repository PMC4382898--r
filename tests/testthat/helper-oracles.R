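# Independent oracles used across the suite.  These deliberately avoid the
# package's scanning code paths: counting works by literal expansion of the
# degenerate PAM plus fixed-string counting, and approximate search by
# exhaustive enumeration of gap placements with vectorized mismatch
# counting (valid for max_gaps <= 1).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protospacer <- function(len = 20L) random_dna(len)

# Both-strand count of literal kmer followed by a PAM-pattern window,
# overlaps included.
oracle_count_kmer_pam <- function(genome, kmer, pam_pattern) {
  pams <- iupac_expand(pam_pattern)
  words <- paste0(kmer, pams)
  n <- 0L
  for (rec in unclass(genome)) {
    for (strand_seq in c(rec, reverse_complement(rec))) {
      n <- n + sum(stringi::stri_count_fixed(strand_seq, words, overlap = TRUE))
    }
  }
  n
}

# Batched literal-scan oracle over many k-mers at once: every k-mer+PAM
# expansion becomes one literal word, and all words are counted on both
# strands with Biostrings' Aho-Corasick dictionary matcher (overlapping
# occurrences included).  Independent of the package's PAM-window scan.
oracle_count_batch <- function(genome, kmers, pam_pattern) {
  pams <- iupac_expand(pam_pattern)
  words <- as.vector(outer(kmers, pams, paste0))
  pd <- Biostrings::PDict(words)
  tot <- integer(length(words))
  for (rec in unclass(genome)) {
    for (strand_seq in c(rec, reverse_complement(rec))) {
      tot <- tot + Biostrings::countPDict(pd, Biostrings::DNAString(strand_seq))
    }
  }
  as.integer(rowSums(matrix(tot, nrow = length(kmers))))
}

# Mismatch counts of `pat` against every window of `s` (both character
# vectors); NA entries in pat are wildcards.
mm_windows <- function(s, pat) {
  n <- length(s); m <- length(pat)
  ns <- n - m + 1L
  if (ns < 1L) return(integer(0))
  mm <- integer(ns)
  for (j in seq_len(m)) {
    if (is.na(pat[j])) next
    mm <- mm + (s[j:(j + ns - 1L)] != pat[j])
  }
  mm
}

# Exhaustive-enumeration approximate search oracle, max_gaps <= 1.
# Returns a data frame record_id/start/end/strand/n_mismatch/n_gap after
# the same >=50%-overlap dedup rule the package documents.
oracle_search <- function(query, genome, max_mismatches, max_gaps) {
  stopifnot(max_gaps <= 1L)
  q <- strsplit(query, "")[[1]]
  m <- length(q)
  all_rows <- list()
  for (rid in names(genome)) {
    rec <- unclass(genome)[[rid]]
    L <- nchar(rec)
    for (strand in c("+", "-")) {
      s <- strsplit(if (strand == "+") rec else reverse_complement(rec), "")[[1]]
      cand <- list()
      add <- function(starts, len, g, mm) {
        keep <- which(mm <= max_mismatches)
        for (i in keep) {
          cand[[length(cand) + 1L]] <<- c(starts[i], starts[i] + len - 1L, g, mm[i])
        }
      }
      ns0 <- length(s) - m + 1L
      if (ns0 >= 1L) add(seq_len(ns0), m, 0L, mm_windows(s, q))
      if (max_gaps >= 1L) {
        for (d in seq_len(m)) {          # one query base unmatched (19-window)
          pat <- q[-d]
          ns <- length(s) - (m - 1L) + 1L
          if (ns >= 1L) add(seq_len(ns), m - 1L, 1L, mm_windows(s, pat))
        }
        for (k in seq_len(m + 1L)) {     # one subject base unmatched (21-window)
          pat <- append(q, NA_character_, after = k - 1L)
          ns <- length(s) - (m + 1L) + 1L
          if (ns >= 1L) add(seq_len(ns), m + 1L, 1L, mm_windows(s, pat))
        }
      }
      if (length(cand) == 0L) next
      cm <- do.call(rbind, cand)
      df <- data.frame(start = cm[, 1], end = cm[, 2], n_gap = cm[, 3],
                       n_mismatch = cm[, 4])
      # per (start, end) the lexicographic best (n_gap, n_mismatch)
      df <- df[order(df$start, df$end, df$n_gap, df$n_mismatch), ]
      df <- df[!duplicated(df[, c("start", "end")]), ]
      if (strand == "-") {
        tmp <- df$start
        df$start <- L - df$end + 1L
        df$end <- L - tmp + 1L
      }
      df$record_id <- rid
      df$strand <- strand
      all_rows[[length(all_rows) + 1L]] <- df
    }
  }
  if (length(all_rows) == 0L) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), n_gap = integer(0)))
  }
  df <- do.call(rbind, all_rows)
  # same dedup semantics, independently written: best-first greedy keep
  ord <- order(df$n_gap, df$n_mismatch, df$start, df$end)
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (df$record_id[k] != df$record_id[i] || df$strand[k] != df$strand[i]) next
      ov <- min(df$end[k], df$end[i]) - max(df$start[k], df$start[i]) + 1L
      shorter <- min(df$end[k] - df$start[k], df$end[i] - df$start[i]) + 1L
      if (ov >= 0.5 * shorter) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- i
  }
  df <- df[unlist(kept), c("record_id", "start", "end", "strand",
                           "n_mismatch", "n_gap")]
  df <- df[order(df$record_id, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# Convenience: canonical hit key for set comparisons
hit_keys <- function(df) {
  sprintf("%s:%d-%d:%s:mm%d:g%d", df$record_id, df$start, df$end, df$strand,
          df$n_mismatch, df$n_gap)
}
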