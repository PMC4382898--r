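# Sequence records, FASTA I/O, IUPAC utilities and the synthetic-genome
# fixture generator.
#
# Sequences are stored as a `genome_collection`: a named character vector of
# normalized nucleotide strings (uppercase, U mapped to T, alphabet strictly
# {A,C,G,T,N}).  Ambiguity codes beyond N are allowed in PAM *patterns* only,
# never in sequences.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T (so RNA-style input is accepted) and validates
#' that the result contains only A, C, G, T or N.  Any other character is an
#' error naming the offending record and position: silent masking would hide
#' data problems.
#'
#' @param seq A single nucleotide string.
#' @param id Record identifier used in error messages.
#' @return The normalized string.
#' @export
normalize_sequence <- function(seq, id = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) {
    stop("record '", id, "': empty sequence", call. = FALSE)
  }
  bad <- stringi::stri_locate_first_regex(s, "[^ACGTN]")[1, 1]
  if (!is.na(bad)) {
    stop("record '", id, "': illegal character '", substr(s, bad, bad),
         "' at position ", bad, call. = FALSE)
  }
  s
}

#' Construct a genome collection
#'
#' A genome collection is an ordered set of named, normalized nucleotide
#' sequences with unique record ids.  It represents either a background
#' genome (multi-record) or a query.
#'
#' @param seqs Character vector of sequences; names are record ids.  A
#'   `DNAStringSet` is also accepted.
#' @return A named character vector of class `genome_collection`.
#' @export
genome_collection <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) stop("no records", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(ids == "")) {
    stop("every record needs an id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- vapply(seq_along(seqs), function(i) normalize_sequence(seqs[[i]], ids[[i]]),
                character(1))
  names(out) <- ids
  class(out) <- "genome_collection"
  out
}

#' @export
print.genome_collection <- function(x, ...) {
  cat("genome_collection:", length(x), "record(s),",
      total_length(x), "bases total\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %8d bp\n", names(x)[i], nchar(x[[i]])))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Total length of a genome collection in bases
#' @param genome A `genome_collection`.
#' @return Integer, sum of record lengths.
#' @export
total_length <- function(genome) {
  sum(nchar(unclass(genome)))
}

#' Read a (multi-record) FASTA file
#'
#' Records are normalized on the way in (uppercase, U to T); characters
#' outside {A,C,G,T,N} are rejected with the record id and position.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_collection`, record order as in the file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  # FASTA headers may carry descriptions; the id is the first token
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  genome_collection(stats::setNames(as.character(set), ids))
}

#' Write a genome collection as FASTA
#' @param genome A `genome_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; N maps to N.  Vectorized.
#'
#' @param seq Character vector over {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("reverse_complement: sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Does a base fall in an IUPAC code's degeneracy set?
#'
#' Used for PAM-pattern matching (N = any, R = A/G, ...).  Vectorized over
#' `base` and `code` in parallel.
#'
#' @param base Concrete base(s), each one of A, C, G, T.
#' @param code IUPAC code character(s).
#' @return Logical vector.
#' @export
iupac_matches <- function(base, code) {
  stopifnot(is.character(base), is.character(code))
  n <- max(length(base), length(code))
  base <- rep_len(toupper(base), n)
  code <- rep_len(toupper(code), n)
  if (any(!base %in% c("A", "C", "G", "T"))) {
    stop("base must be one of A, C, G, T", call. = FALSE)
  }
  unknown <- !code %in% names(IUPAC_SETS)
  if (any(unknown)) {
    stop("unknown IUPAC code: ", paste(unique(code[unknown]), collapse = ", "),
         call. = FALSE)
  }
  mapply(function(b, cd) b %in% IUPAC_SETS[[cd]], base, code, USE.NAMES = FALSE)
}

#' Translate an IUPAC pattern into a regular expression
#'
#' Each degenerate code becomes a character class over its concrete bases;
#' classes never include N, so a sequence window containing N never matches
#' any pattern (a deliberate, conservative rule).
#'
#' @param pattern IUPAC string, e.g. "NGG".
#' @return A regex string.
#' @export
iupac_to_regex <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  codes <- strsplit(toupper(pattern), "")[[1]]
  unknown <- !codes %in% names(IUPAC_SETS)
  if (any(unknown)) {
    stop("unknown IUPAC code in pattern: ",
         paste(unique(codes[unknown]), collapse = ", "), call. = FALSE)
  }
  paste(vapply(codes, function(cd) {
    set <- IUPAC_SETS[[cd]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Expand an IUPAC pattern into all concrete strings
#' @param pattern IUPAC string.
#' @return Character vector of every concrete expansion.
#' @export
iupac_expand <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  sets <- lapply(codes, function(cd) {
    if (!cd %in% names(IUPAC_SETS)) stop("unknown IUPAC code: ", cd, call. = FALSE)
    IUPAC_SETS[[cd]]
  })
  apply(expand.grid(rev(sets), stringsAsFactors = FALSE), 1L,
        function(r) paste(rev(r), collapse = ""))
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe sites to plant in a synthetic genome
#'
#' A plant spec describes one protospacer and how it should appear in the
#' fixture genome: exact full-length copies (protospacer + PAM), copies that
#' share only the 12-mer seed adjacent to the PAM, and near-match copies
#' carrying defined point mutations.
#'
#' @param protospacer The 20-mer target sequence (protospacer strand).
#' @param pam Concrete PAM bases planted 3' of the protospacer (e.g. "TGG").
#' @param copies_full Number of exact protospacer+PAM plantings.
#' @param copies_seed_only Number of plantings sharing only the 12-mer
#'   seed+PAM (the 5' 8 bases are randomized with at least one mismatch).
#' @param mutations Data frame with columns `offset` (0-based position in the
#'   protospacer) and `base`; one near-match copy is planted with all these
#'   edits applied.  `NULL` for none.
#' @param strand Strand(s) on which to plant, recycled across plantings.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(protospacer, pam, copies_full = 0L, copies_seed_only = 0L,
                       mutations = NULL, strand = "+") {
  protospacer <- normalize_sequence(protospacer, "protospacer")
  pam <- normalize_sequence(pam, "pam")
  if (grepl("N", protospacer) || grepl("N", pam)) {
    stop("planted sequences may not contain N", call. = FALSE)
  }
  if (!is.null(mutations)) {
    mutations <- as.data.frame(mutations)
    stopifnot(all(c("offset", "base") %in% names(mutations)))
    if (any(mutations$offset < 0L | mutations$offset >= nchar(protospacer))) {
      stop("mutation offsets must lie in [0, target length)", call. = FALSE)
    }
  }
  stopifnot(all(strand %in% c("+", "-")))
  structure(list(protospacer = protospacer, pam = pam,
                 copies_full = as.integer(copies_full),
                 copies_seed_only = as.integer(copies_seed_only),
                 mutations = mutations, strand = strand),
            class = "plant_spec")
}

# Site sequences (protospacer strand, target+PAM) implied by a plant spec.
# Returns a data.frame(kind, site_seq).
plant_sites <- function(spec, seed_len = 12L) {
  m <- nchar(spec$protospacer)
  sites <- character(0); kinds <- character(0)
  if (spec$copies_full > 0L) {
    sites <- c(sites, rep(paste0(spec$protospacer, spec$pam), spec$copies_full))
    kinds <- c(kinds, rep("full", spec$copies_full))
  }
  if (spec$copies_seed_only > 0L) {
    seed <- substr(spec$protospacer, m - seed_len + 1L, m)
    pre_len <- m - seed_len
    for (i in seq_len(spec$copies_seed_only)) {
      repeat {
        pre <- paste(sample(c("A", "C", "G", "T"), pre_len, replace = TRUE),
                     collapse = "")
        if (pre != substr(spec$protospacer, 1L, pre_len)) break
      }
      sites <- c(sites, paste0(pre, seed, spec$pam))
      kinds <- c(kinds, "seed_only")
    }
  }
  if (!is.null(spec$mutations) && nrow(spec$mutations) > 0L) {
    mut <- strsplit(spec$protospacer, "")[[1]]
    for (r in seq_len(nrow(spec$mutations))) {
      mut[spec$mutations$offset[r] + 1L] <- toupper(spec$mutations$base[r])
    }
    sites <- c(sites, paste0(paste(mut, collapse = ""), spec$pam))
    kinds <- c(kinds, "mutant")
  }
  data.frame(kind = kinds, site_seq = sites, stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted target sites
#'
#' Draws a uniform-random {A,C,G,T} background of the requested length,
#' inserts every planting at a non-overlapping position on its requested
#' strand, and returns the genome together with a ground-truth manifest.
#' After planting, the background is scrubbed: any accidental occurrence of
#' a planted k-mer+PAM (full length and each seed length, both strands) that
#' is not a manifest site gets one background base mutated, so exact-count
#' recovery against the manifest is guaranteed.  Deterministic for a fixed
#' seed.
#'
#' @param length Genome length in bases (one record).
#' @param plants A `plant_spec` or list of them.
#' @param seed Integer RNG seed.
#' @param record_id Record id of the emitted genome.
#' @param pam_pattern IUPAC PAM pattern the fixture is clean under.
#' @param seed_lens Seed lengths the fixture is clean under.
#' @param min_gap Minimum background gap between planted spans.
#' @return A list with `genome` (a `genome_collection`) and `manifest` (a
#'   data frame in BED6 layout — chrom, start, end, name, score, strand, all
#'   0-based half-open — plus `kind` and `site_seq` columns).
#' @export
make_synthetic_genome <- function(length, plants, seed, record_id = "synth1",
                                  pam_pattern = "NGG", seed_lens = c(12L, 8L),
                                  min_gap = 30L) {
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  stopifnot(all(vapply(plants, inherits, logical(1), "plant_spec")))
  with_seed(seed, {
    sites_df <- do.call(rbind, lapply(seq_along(plants), function(i) {
      df <- plant_sites(plants[[i]], seed_len = max(seed_lens))
      if (nrow(df) == 0L) return(NULL)
      df$spec <- i
      df$strand <- rep_len(plants[[i]]$strand, nrow(df))
      df
    }))
    n_sites <- if (is.null(sites_df)) 0L else nrow(sites_df)
    site_len <- if (n_sites) nchar(sites_df$site_seq) else integer(0)
    if (n_sites && length < sum(site_len + min_gap) + min_gap) {
      stop("genome length ", length, " too small to hold ", n_sites,
           " plantings without overlap", call. = FALSE)
    }
    bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE)

    # place plantings left to right with jittered gaps: non-overlap by design
    starts <- integer(n_sites)
    if (n_sites) {
      ord <- sample.int(n_sites)  # random genome order of the plantings
      slack <- length - sum(site_len) - min_gap * (n_sites + 1L)
      gaps <- if (slack > 0L) {
        u <- c(sort(sample.int(slack, n_sites, replace = TRUE)), slack)
        min_gap + diff(c(0L, u))
      } else rep(min_gap, n_sites + 1L)
      pos <- 1L
      for (j in seq_len(n_sites)) {
        i <- ord[j]
        pos <- pos + gaps[j]
        starts[i] <- pos
        ins <- sites_df$site_seq[i]
        if (sites_df$strand[i] == "-") ins <- reverse_complement(ins)
        bg[starts[i]:(starts[i] + site_len[i] - 1L)] <- strsplit(ins, "")[[1]]
        pos <- pos + site_len[i]
      }
    }

    manifest <- if (n_sites) {
      counts <- stats::ave(seq_len(n_sites), paste(sites_df$spec, sites_df$kind),
                           FUN = seq_along)
      data.frame(
        chrom = record_id,
        start = starts - 1L,                      # BED: 0-based half-open
        end = starts - 1L + site_len,
        name = sprintf("plant%02d_%s%02d", sites_df$spec, sites_df$kind, counts),
        score = 0L,
        strand = sites_df$strand,
        kind = sites_df$kind,
        site_seq = sites_df$site_seq,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0), score = integer(0), strand = character(0),
                 kind = character(0), site_seq = character(0))
    }

    bg <- scrub_background(bg, manifest, plants, pam_pattern, seed_lens)
    genome <- genome_collection(stats::setNames(paste(bg, collapse = ""), record_id))
    list(genome = genome, manifest = manifest[order(manifest$start), , drop = FALSE])
  })
}

# Remove accidental background occurrences of planted k-mer+PAM words.
# `bg` is the genome as a character vector; manifest spans are never touched.
scrub_background <- function(bg, manifest, plants, pam_pattern, seed_lens,
                             max_rounds = 100L) {
  L <- length(bg)
  protected <- rep(FALSE, L)
  for (r in seq_len(nrow(manifest))) {
    protected[(manifest$start[r] + 1L):manifest$end[r]] <- TRUE
  }
  # words to keep background-free: suffix_k(protospacer) for each spec & k
  words <- unique(unlist(lapply(plants, function(sp) {
    m <- nchar(sp$protospacer)
    vapply(c(m, seed_lens), function(k) substr(sp$protospacer, m - k + 1L, m),
           character(1))
  })))
  if (length(words) == 0L) return(bg)
  pam_re <- iupac_to_regex(pam_pattern)
  # manifest-sanctioned plus/minus word occurrences are those inside manifest
  # spans; everything else is accidental and gets one free base mutated.
  for (round in seq_len(max_rounds)) {
    s <- paste(bg, collapse = "")
    rc <- reverse_complement(s)
    dirty <- FALSE
    for (w in words) {
      for (strand in c("+", "-")) {
        subject <- if (strand == "+") s else rc
        hits <- gregexpr(paste0("(?=", w, pam_re, ")"), subject, perl = TRUE)[[1]]
        if (hits[1] == -1L) next
        span_len <- nchar(w) + nchar(pam_pattern)
        for (p in as.integer(hits)) {
          lo <- if (strand == "+") p else L - (p + span_len - 1L) + 1L
          idx <- lo:(lo + span_len - 1L)
          if (all(protected[idx])) next          # fully inside a planted span
          free <- idx[!protected[idx]]
          bg[free[1L]] <- sample(setdiff(c("A", "C", "G", "T"), bg[free[1L]]), 1L)
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(bg)
  }
  stop("could not scrub background after ", max_rounds, " rounds", call. = FALSE)
}

#' Ground-truth hit counts implied by a fixture manifest
#'
#' For a protospacer, counts how often each suffix k-mer + PAM occurs fully
#' inside the planted spans (both orientations of each planted site).  The
#' generator scrubs the background, so these are exactly the counts a
#' genome-wide scan of the fixture must report.  In typical fixtures this
#' reduces to the declared copy numbers (full copies for k = target length;
#' full + seed-only copies for the seed lengths).
#'
#' @param manifest Manifest data frame from [make_synthetic_genome()].
#' @param protospacer The planted 20-mer.
#' @param pam_pattern IUPAC PAM pattern.
#' @param k_values K-mer lengths to count.
#' @return Named integer vector, one count per k.
#' @export
manifest_expected_counts <- function(manifest, protospacer,
                                     pam_pattern = "NGG",
                                     k_values = c(20L, 12L, 8L)) {
  m <- nchar(protospacer)
  pam_re <- iupac_to_regex(pam_pattern)
  out <- stats::setNames(integer(length(k_values)), as.character(k_values))
  for (k in k_values) {
    w <- substr(protospacer, m - k + 1L, m)
    re <- paste0("(?=", w, pam_re, ")")
    n <- 0L
    for (site in manifest$site_seq) {
      for (subject in c(site, reverse_complement(site))) {
        h <- gregexpr(re, subject, perl = TRUE)[[1]]
        if (h[1] != -1L) n <- n + length(h)
      }
    }
    out[[as.character(k)]] <- n
  }
  out
}

#' Write a manifest (or any BED6 data frame) to a BED file
#' @param bed Data frame with chrom, start, end, name, score, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path Path to a BED file.
#' @return Data frame with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"))
}
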