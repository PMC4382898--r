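# Candidate enumeration: every 20-mer lying immediately 5' of a PAM on
# either strand of the query, annotated with GC content, nearest-neighbor
# melting temperature and the pol III terminator (TTTT) flag.

#' Design parameters
#'
#' Bundles every tunable of a design run.  Defaults follow S. pyogenes Cas9
#' practice: 20-nt protospacer, NGG PAM (NRG optional), seed uniqueness
#' judged at 12 and 8 nt adjacent to the PAM.
#'
#' @param pam_pattern IUPAC PAM pattern, default "NGG".
#' @param target_len Protospacer length in bases, default 20.
#' @param seed_lens Seed lengths (strictly decreasing), default c(12, 8).
#' @param max_query_len Maximum accepted query length, default 10000 bases.
#' @param tm_na_mM Sodium concentration for the Tm calculation, mM.
#' @param tm_oligo_uM Total oligo strand concentration for Tm, micromolar.
#' @return A list of class `design_params`.
#' @export
design_params <- function(pam_pattern = "NGG", target_len = 20L,
                          seed_lens = c(12L, 8L), max_query_len = 10000L,
                          tm_na_mM = 50, tm_oligo_uM = 0.5) {
  pam_pattern <- toupper(pam_pattern)
  iupac_to_regex(pam_pattern)  # validates codes
  target_len <- as.integer(target_len)
  seed_lens <- as.integer(seed_lens)
  stopifnot(
    target_len >= max(seed_lens),
    length(seed_lens) >= 1L, all(diff(seed_lens) < 0L),
    nchar(pam_pattern) >= 1L,
    max_query_len > target_len + nchar(pam_pattern),
    tm_na_mM > 0, tm_oligo_uM > 0
  )
  structure(list(pam_pattern = pam_pattern, target_len = target_len,
                 seed_lens = seed_lens, max_query_len = as.integer(max_query_len),
                 tm_na_mM = tm_na_mM, tm_oligo_uM = tm_oligo_uM,
                 tm_method = "nearest-neighbor, SantaLucia 1998 unified"),
            class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat("design_params: PAM", x$pam_pattern, "| target", x$target_len, "nt | seeds",
      paste(x$seed_lens, collapse = "/"), "nt | Tm at", x$tm_na_mM, "mM Na+,",
      x$tm_oligo_uM, "uM oligo\n")
  invisible(x)
}

#' GC content of a sequence, percent
#'
#' @param seq Character vector of nucleotide strings over {A,C,G,T}.
#' @return Numeric vector, 100 * (G+C)/length, rounded to one decimal.
#'   Sequences containing N give NA.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq))
  gc <- stringi::stri_count_regex(seq, "[GC]")
  out <- round(100 * gc / nchar(seq), 1)
  out[stringi::stri_detect_fixed(seq, "N")] <- NA_real_
  out
}

#' Four-consecutive-T (pol III terminator) flag
#'
#' RNA polymerase III terminates on a run of four T's, truncating gRNAs
#' expressed from pol III promoters, so protospacers containing TTTT should
#' be avoided in such vectors.  Checked on the protospacer-strand sequence.
#'
#' @param seq Character vector over {A,C,G,T,N}.
#' @return Logical vector: TRUE iff "TTTT" occurs as a substring.
#' @export
has_poly_t <- function(seq) {
  stopifnot(is.character(seq))
  stringi::stri_detect_fixed(seq, "TTTT")
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(K*mol), per propagation step 5'->3'.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation with a terminal G.C vs terminal A.T, per end
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from unified nearest-neighbor thermodynamics:
#' Tm = 1000 * dH / (dS + R * ln(CT/4)) - 273.15, with dH/dS summed over
#' dinucleotide steps plus terminal initiation terms, and the entropy salt
#' correction dS + 0.368 * (N-1) * ln([Na+]).  CT/4 assumes two distinct,
#' non-self-complementary strands at equal concentration.
#'
#' @param seq Character vector over {A,C,G,T}, each of length >= 2.
#' @param params A `design_params` (supplies Na+ mM and oligo uM).
#' @return Numeric vector of Tm in degrees Celsius, one decimal; NA for
#'   sequences containing N.
#' @export
melting_temperature <- function(seq, params = design_params()) {
  stopifnot(is.character(seq))
  R <- 1.987  # cal/(K*mol)
  ct <- params$tm_oligo_uM * 1e-6
  na <- params$tm_na_mM / 1000
  vapply(seq, function(s) {
    if (stringi::stri_detect_fixed(s, "N")) return(NA_real_)
    n <- nchar(s)
    stopifnot(n >= 2L)
    steps <- substring(s, 1:(n - 1L), 2:n)
    ends <- c(substr(s, 1L, 1L), substr(s, n, n))
    endclass <- ifelse(ends %in% c("G", "C"), "GC", "AT")
    dh <- sum(NN_DH[steps]) + sum(NN_INIT_DH[endclass])
    ds <- sum(NN_DS[steps]) + sum(NN_INIT_DS[endclass])
    ds <- ds + 0.368 * (n - 1L) * log(na)
    round(1000 * dh / (ds + R * log(ct / 4)) - 273.15, 1)
  }, numeric(1), USE.NAMES = FALSE)
}

# 1-based start positions of PAM-pattern matches in a strand sequence
# (overlaps included; windows containing N never match).
pam_positions <- function(seq, pam_pattern) {
  hits <- gregexpr(paste0("(?=", iupac_to_regex(pam_pattern), ")"), seq,
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Enumerate PAM-adjacent target candidates in a query
#'
#' Scans both strands of the query for every position where a full-length
#' protospacer (no N) lies immediately 5' of a window matching the PAM
#' pattern.  Coordinates are 1-based inclusive on the query's plus strand
#' and span protospacer+PAM.  Candidates are sorted by start ascending, "+"
#' before "-" at ties.  Hit-count columns are NA until filled by
#' [annotate_and_highlight()].
#'
#' @param query A `genome_collection` with one record, or a single named or
#'   unnamed nucleotide string.
#' @param params A `design_params`.
#' @return A data frame of class `target_candidates`: start, end, strand,
#'   target_seq, pam_seq, gc_percent, tm_celsius, has_tttt, hits_full,
#'   hits_seed12, hits_seed8, highlighted, zero_hit_warning.
#' @export
enumerate_candidates <- function(query, params = design_params()) {
  if (is.character(query) && !inherits(query, "genome_collection")) {
    if (is.null(names(query))) names(query) <- "query"
    query <- genome_collection(query)
  }
  stopifnot(inherits(query, "genome_collection"), length(query) == 1L)
  qid <- names(query)[1]
  s <- unclass(query)[[1]]
  L <- nchar(s)
  if (L > params$max_query_len) {
    stop("query '", qid, "' is ", L, " bases; the limit is ",
         params$max_query_len, " bases (10 kbp by default)", call. = FALSE)
  }
  m <- params$target_len
  plen <- nchar(params$pam_pattern)
  span <- m + plen

  scan_strand <- function(strand_seq, strand) {
    p <- pam_positions(strand_seq, params$pam_pattern)
    p <- p[p - m >= 1L & p + plen - 1L <= nchar(strand_seq)]
    if (length(p) == 0L) return(NULL)
    tg <- substring(strand_seq, p - m, p - 1L)
    pm <- substring(strand_seq, p, p + plen - 1L)
    keep <- !stringi::stri_detect_fixed(tg, "N")
    p <- p[keep]; tg <- tg[keep]; pm <- pm[keep]
    if (length(p) == 0L) return(NULL)
    if (strand == "+") {
      start <- p - m
    } else {
      # span on the minus-strand scan maps to plus coords by reflection
      start <- L - (p + plen - 1L) + 1L
    }
    data.frame(start = start, end = start + span - 1L, strand = strand,
               target_seq = tg, pam_seq = pm, stringsAsFactors = FALSE)
  }

  cand <- rbind(scan_strand(s, "+"),
                scan_strand(reverse_complement(s), "-"))
  if (is.null(cand) || nrow(cand) == 0L) {
    cand <- data.frame(start = integer(0), end = integer(0),
                       strand = character(0), target_seq = character(0),
                       pam_seq = character(0), stringsAsFactors = FALSE)
  }
  cand <- cand[order(cand$start, cand$strand), , drop = FALSE]
  rownames(cand) <- NULL
  cand$gc_percent <- gc_content(cand$target_seq)
  cand$tm_celsius <- melting_temperature(cand$target_seq, params)
  cand$has_tttt <- has_poly_t(cand$target_seq)
  cand$hits_full <- rep(NA_integer_, nrow(cand))
  cand$hits_seed12 <- rep(NA_integer_, nrow(cand))
  cand$hits_seed8 <- rep(NA_integer_, nrow(cand))
  cand$highlighted <- rep(NA, nrow(cand))
  cand$zero_hit_warning <- rep(NA, nrow(cand))
  attr(cand, "params") <- params
  attr(cand, "query_id") <- qid
  attr(cand, "query_length") <- L
  class(cand) <- c("target_candidates", "data.frame")
  cand
}
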