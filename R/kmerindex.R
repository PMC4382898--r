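# Genome-wide exact counting of (k-mer, PAM) occurrences for the full
# target length and each seed length, and candidate scoring from those
# counts.  The index stores only k-mers observed immediately 5' of a PAM
# window, so its size is bounded by the number of PAM sites, not by 4^k.

genome_checksum <- function(genome) {
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(paste0(">", names(genome), "\n", unclass(genome)), tf)
  unname(tools::md5sum(tf))
}

#' Build a k-mer + PAM occurrence index over a genome
#'
#' Single pass over each strand of every record: at every position where a
#' window matches the PAM pattern (no N), the k bases immediately 5' of the
#' window (no N, fully inside the record) are counted, for each k in
#' {target_len} union seed_lens.  Both strands are scanned, so the index is
#' invariant under reverse-complementing any record.  Overlapping PAM
#' windows all count (GGGG holds two GG windows under NGG).
#'
#' @param genome A `genome_collection`.
#' @param params A `design_params`.
#' @return A list of class `kmer_pam_index` with `counts` (per-k named
#'   integer vectors), `k_values`, `pam_pattern`, `params`, `genome_id`.
#' @export
build_index <- function(genome, params = design_params()) {
  stopifnot(inherits(genome, "genome_collection"))
  k_values <- sort(unique(c(params$target_len, params$seed_lens)),
                   decreasing = TRUE)
  plen <- nchar(params$pam_pattern)
  kmers <- stats::setNames(vector("list", length(k_values)),
                           as.character(k_values))
  for (rec in unclass(genome)) {
    for (strand_seq in c(rec, reverse_complement(rec))) {
      p <- pam_positions(strand_seq, params$pam_pattern)
      p <- p[p + plen - 1L <= nchar(strand_seq)]
      for (k in k_values) {
        pk <- p[p - k >= 1L]
        if (length(pk) == 0L) next
        km <- substring(strand_seq, pk - k, pk - 1L)
        km <- km[!stringi::stri_detect_fixed(km, "N")]
        kk <- as.character(k)
        kmers[[kk]] <- c(kmers[[kk]], km)
      }
    }
  }
  counts <- lapply(kmers, function(v) {
    if (is.null(v)) return(stats::setNames(integer(0), character(0)))
    tb <- table(v)
    stats::setNames(as.integer(tb), names(tb))
  })
  structure(list(counts = counts, k_values = k_values,
                 pam_pattern = params$pam_pattern, params = params,
                 genome_id = genome_checksum(genome)),
            class = "kmer_pam_index")
}

#' @export
print.kmer_pam_index <- function(x, ...) {
  cat("kmer_pam_index: PAM", x$pam_pattern, "| k =",
      paste(x$k_values, collapse = ", "), "| genome", x$genome_id, "\n")
  for (k in names(x$counts)) {
    cat(sprintf("  k=%s: %d distinct k-mers, %d occurrences\n",
                k, length(x$counts[[k]]), sum(x$counts[[k]])))
  }
  invisible(x)
}

#' Look up hit counts for a target sequence
#'
#' Exact genome-wide occurrence counts of the full target+PAM and of the
#' seed k-mers (the 3'-most bases, adjacent to the PAM) + PAM.  A k-mer
#' absent from the index has zero occurrences.
#'
#' @param index A `kmer_pam_index`.
#' @param target_seq String of exactly target_len bases.
#' @return Named integer vector: `full`, then `seed<k>` per seed length
#'   (default `seed12`, `seed8`).
#' @export
lookup_hits <- function(index, target_seq) {
  m <- index$params$target_len
  if (nchar(target_seq) != m) {
    stop("target_seq must be exactly ", m, " bases, got ", nchar(target_seq),
         call. = FALSE)
  }
  get1 <- function(k, kmer) {
    v <- index$counts[[as.character(k)]][kmer]
    if (is.na(v)) 0L else as.integer(v)
  }
  out <- c(full = get1(m, target_seq))
  for (k in index$params$seed_lens) {
    out[[paste0("seed", k)]] <- get1(k, substr(target_seq, m - k + 1L, m))
  }
  out
}

#' Fill hit counts and highlighting on a candidate table
#'
#' Fills hits_full / hits_seed12 / hits_seed8 for each candidate from the
#' index.  A candidate is highlighted when it is unique at full length and
#' at the 12-mer seed (hits_full == 1 and hits_seed12 == 1): counts include
#' the intended site itself, so 1 means "only the intended target".  Zero
#' full-length hits raise zero_hit_warning: the query sequence does not
#' occur in the genome at all (e.g. it spans an exon-exon junction), so such
#' candidates should be avoided.  The 8-mer seed count is reported but not
#' gated: 8-mer uniqueness is rarely achievable in large genomes.
#'
#' @param candidates A `target_candidates` data frame from
#'   [enumerate_candidates()].
#' @param index A `kmer_pam_index` built with the same `design_params`.
#' @return The candidate table with counts, `highlighted` and
#'   `zero_hit_warning` filled; ordering preserved.
#' @export
annotate_and_highlight <- function(candidates, index) {
  stopifnot(inherits(candidates, "target_candidates"),
            inherits(index, "kmer_pam_index"))
  cp <- attr(candidates, "params")
  ip <- index$params
  if (!identical(cp$pam_pattern, ip$pam_pattern) ||
      !identical(cp$target_len, ip$target_len) ||
      !identical(cp$seed_lens, ip$seed_lens)) {
    stop("candidates and index were built with different design parameters",
         call. = FALSE)
  }
  if (nrow(candidates) > 0L) {
    # lookup_hits returns (full, seed<k>...) in params order
    hits <- t(vapply(candidates$target_seq,
                     function(t) unname(lookup_hits(index, t)),
                     integer(1L + length(ip$seed_lens)), USE.NAMES = FALSE))
    candidates$hits_full <- hits[, 1L]
    candidates$hits_seed12 <- hits[, 2L]
    candidates$hits_seed8 <- if (length(ip$seed_lens) >= 2L) hits[, 3L] else
      candidates$hits_seed12
    candidates$highlighted <- candidates$hits_full == 1L &
      candidates$hits_seed12 == 1L
    candidates$zero_hit_warning <- candidates$hits_full == 0L
  }
  attr(candidates, "genome_id") <- index$genome_id
  candidates
}

#' Serialize an index to a flat text file
#'
#' Versioned tab-separated format: header lines (format version, PAM
#' pattern, target/seed lengths, Tm conditions, genome checksum) followed by
#' one `k <TAB> kmer <TAB> count` line per entry.
#'
#' @param index A `kmer_pam_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  p <- index$params
  hdr <- c("#kmer_pam_index\tv1",
           paste0("#pam_pattern\t", p$pam_pattern),
           paste0("#target_len\t", p$target_len),
           paste0("#seed_lens\t", paste(p$seed_lens, collapse = ",")),
           paste0("#tm_na_mM\t", p$tm_na_mM),
           paste0("#tm_oligo_uM\t", p$tm_oligo_uM),
           paste0("#genome_id\t", index$genome_id))
  body <- unlist(lapply(names(index$counts), function(k) {
    v <- index$counts[[k]]
    if (length(v) == 0L) return(character(0))
    paste(k, names(v), v, sep = "\t")
  }))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an index written by [write_index()]
#' @param path Path to a serialized index.
#' @return A `kmer_pam_index`.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#kmer_pam_index")) {
    stop("not a kmer_pam_index file: ", path, call. = FALSE)
  }
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  hv <- do.call(rbind, strsplit(hdr, "\t", fixed = TRUE))
  field <- function(key) hv[hv[, 1] == paste0("#", key), 2]
  params <- design_params(
    pam_pattern = field("pam_pattern"),
    target_len = as.integer(field("target_len")),
    seed_lens = as.integer(strsplit(field("seed_lens"), ",")[[1]]),
    tm_na_mM = as.numeric(field("tm_na_mM")),
    tm_oligo_uM = as.numeric(field("tm_oligo_uM"))
  )
  k_values <- sort(unique(c(params$target_len, params$seed_lens)),
                   decreasing = TRUE)
  counts <- stats::setNames(
    lapply(k_values, function(k) stats::setNames(integer(0), character(0))),
    as.character(k_values))
  if (length(body) > 0L) {
    bv <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    for (k in unique(bv[, 1])) {
      rows <- bv[, 1] == k
      counts[[k]] <- stats::setNames(as.integer(bv[rows, 3]), bv[rows, 2])
    }
  }
  structure(list(counts = counts, k_values = k_values,
                 pam_pattern = params$pam_pattern, params = params,
                 genome_id = field("genome_id")),
            class = "kmer_pam_index")
}
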