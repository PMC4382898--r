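# Mismatch/gap-tolerant search versus the enumeration oracle.

test_that("an exactly planted query is one all-match hit", {
  ps <- "ACGTTGCAGATCCGGATTCA"
  fx <- make_synthetic_genome(6000, plant_spec(ps, "TGG", copies_full = 1),
                              seed = 5)
  hits <- search_approximate(ps, fx$genome, alignment_budget(3, 1))
  r <- fx$manifest[1, ]
  planted <- hits[hits$start == r$start + 1L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$n_mismatch, 0L)
  expect_equal(planted$n_gap, 0L)
  expect_equal(planted$marker_line, strrep("|", 20))
  expect_equal(planted$aligned_subject, ps)
  expect_equal(planted$pam_at_site, "TGG")
  expect_true(planted$pam_ok)
})

test_that("a single substitution is found and marked at the right column", {
  ps <- "ACGTTGCAGATCCGGATTCA"
  mutated <- ps
  substr(mutated, 12, 12) <- "G"   # query offset 11 (0-based); C -> G
  g <- genome_collection(c(r = paste0(strrep("A", 40), mutated, "TGG",
                                      strrep("C", 40))))
  hits <- search_approximate(ps, g, alignment_budget(3, 1))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$n_mismatch, 1L)
  expect_equal(plus$n_gap, 0L)
  expect_equal(substr(plus$marker_line, 12, 12), "X")
  expect_equal(gsub("X", "|", plus$marker_line), strrep("|", 20))
})

test_that("a single deletion is found as one gap with '-' in the subject", {
  ps <- "ACGTTGCAGATCCGGATTCA"
  deleted <- paste0(substr(ps, 1, 9), substr(ps, 11, 20))  # drop base 10
  g <- genome_collection(c(r = paste0(strrep("T", 35), deleted, "CGG",
                                      strrep("A", 35))))
  hits <- search_approximate(ps, g, alignment_budget(3, 1))
  gap <- hits[hits$n_gap == 1L, ]
  expect_equal(nrow(gap), 1L)
  expect_equal(gap$n_mismatch, 0L)
  expect_true(grepl("-", gap$aligned_subject, fixed = TRUE))
  expect_false(grepl("-", gap$aligned_query, fixed = TRUE))
  expect_equal(gsub("-", "", gap$aligned_subject), deleted)
  expect_equal(gap$aligned_query, ps)
})

test_that("an insertion in the genome appears as a gap in the aligned query", {
  ps <- "GATTACACCGATGGATCCTA"
  inserted <- paste0(substr(ps, 1, 13), "T", substr(ps, 14, 20))
  g <- genome_collection(c(r = paste0(strrep("A", 30), inserted, "TGG",
                                      strrep("C", 30))))
  hits <- search_approximate(ps, g, alignment_budget(3, 1))
  gap <- hits[hits$n_gap == 1L, ]
  expect_equal(nrow(gap), 1L)
  expect_true(grepl("-", gap$aligned_query, fixed = TRUE))
  expect_equal(gsub("-", "", gap$aligned_query), ps)
})

test_that("search agrees with the enumeration oracle on random genomes with plants", {
  set.seed(909)
  for (trial in 1:6) {
    ps <- random_protospacer()
    nmut <- sample(0:3, 1)
    muts <- if (nmut > 0) {
      data.frame(offset = sample(0:19, nmut),
                 base = sample(c("A", "C", "G", "T"), nmut, replace = TRUE))
    } else NULL
    fx <- make_synthetic_genome(
      7000,
      list(plant_spec(ps, "TGG", copies_full = 1, strand = sample(c("+", "-"), 1)),
           plant_spec(ps, "AGG", copies_seed_only = 1, mutations = muts)),
      seed = 1000 + trial)
    for (budget in list(alignment_budget(3, 1), alignment_budget(2, 0),
                        alignment_budget(3, 0), alignment_budget(1, 1))) {
      got <- search_approximate(ps, fx$genome, budget)
      want <- oracle_search(ps, fx$genome, budget$max_mismatches,
                            budget$max_gaps)
      expect_identical(hit_keys(got), hit_keys(want),
                       info = sprintf("trial %d mm=%d g=%d", trial,
                                      budget$max_mismatches, budget$max_gaps))
    }
  }
})

test_that("hit sets grow monotonically with either budget component", {
  ps <- "ACGTTGCAGATCCGGATTCA"
  fx <- make_synthetic_genome(
    6000,
    plant_spec(ps, "TGG", copies_full = 1,
               mutations = data.frame(offset = c(3, 12), base = c("T", "A"))),
    seed = 404)
  loci <- function(df) paste(df$record_id, df$start, df$strand)
  h0 <- search_approximate(ps, fx$genome, alignment_budget(0, 0))
  h2 <- search_approximate(ps, fx$genome, alignment_budget(2, 0))
  h21 <- search_approximate(ps, fx$genome, alignment_budget(2, 1))
  h31 <- search_approximate(ps, fx$genome, alignment_budget(3, 1))
  expect_true(all(loci(h0) %in% loci(h2)))
  expect_true(all(loci(h2) %in% loci(h21)))
  expect_true(all(loci(h21) %in% loci(h31)))
  expect_gt(nrow(h31), nrow(h0))
})

test_that("strand symmetry: hits on the reverse-complemented genome mirror", {
  set.seed(77)
  ps <- random_protospacer()
  fx <- make_synthetic_genome(
    5000, plant_spec(ps, "TGG", copies_full = 2, strand = c("+", "-")),
    seed = 606)
  L <- total_length(fx$genome)
  grc <- genome_collection(stats::setNames(
    reverse_complement(unclass(fx$genome)[[1]]), names(fx$genome)))
  a <- search_approximate(ps, fx$genome, alignment_budget(3, 1))
  b <- search_approximate(ps, grc, alignment_budget(3, 1))
  key_a <- sort(sprintf("%d-%d:%s:%d:%d", a$start, a$end, a$strand,
                        a$n_mismatch, a$n_gap))
  key_b <- sort(sprintf("%d-%d:%s:%d:%d", L - b$end + 1L, L - b$start + 1L,
                        ifelse(b$strand == "+", "-", "+"),
                        b$n_mismatch, b$n_gap))
  expect_equal(key_a, key_b)
})

test_that("require_pam keeps only hits with a pattern-matching PAM", {
  ps <- "CCATAGACTCAGTACGATCA"
  # same near-match twice: once with a PAM, once with TTT following
  site_mm <- ps
  substr(site_mm, 5, 5) <- "G"
  g <- genome_collection(c(r = paste0(strrep("A", 30), site_mm, "TGG",
                                      strrep("A", 20), site_mm, "TTT",
                                      strrep("A", 30))))
  all_hits <- search_approximate(ps, g, alignment_budget(3, 1))
  expect_equal(nrow(all_hits[all_hits$strand == "+", ]), 2L)
  pam_hits <- search_approximate(ps, g, alignment_budget(3, 1,
                                                         require_pam = TRUE))
  expect_equal(nrow(pam_hits[pam_hits$strand == "+", ]), 1L)
  expect_true(all(pam_hits$pam_ok))
})

test_that("zero-budget PAM-required search equals the exact index count", {
  set.seed(211)
  for (trial in 1:3) {
    ps <- random_protospacer()
    fx <- make_synthetic_genome(
      8000, plant_spec(ps, "CGG", copies_full = trial, copies_seed_only = 1),
      seed = 300 + trial)
    params <- design_params()
    idx <- build_index(fx$genome, params)
    expect_true(count_consistency_check(ps, fx$genome, params, idx))
    expect_equal(unname(lookup_hits(idx, ps)["full"]), trial)
    # and a target absent from the genome agrees at zero
    expect_true(count_consistency_check("GCGCGCGCGCATATATATAT", fx$genome,
                                        params, idx))
  }
})

test_that("alignment strings reproduce the query and satisfy length invariants", {
  set.seed(505)
  ps <- random_protospacer()
  fx <- make_synthetic_genome(
    6000,
    plant_spec(ps, "TGG", copies_full = 1,
               mutations = data.frame(offset = 7, base = "A")),
    seed = 707)
  hits <- search_approximate(ps, fx$genome, alignment_budget(3, 1))
  expect_gt(nrow(hits), 0)
  for (i in seq_len(nrow(hits))) {
    expect_equal(nchar(hits$aligned_query[i]), nchar(hits$aligned_subject[i]))
    expect_equal(nchar(hits$aligned_query[i]), nchar(hits$marker_line[i]))
    expect_equal(gsub("-", "", hits$aligned_query[i]), ps)
    expect_equal(hits$n_mismatch[i],
                 lengths(regmatches(hits$marker_line[i],
                                    gregexpr("X", hits$marker_line[i]))))
    expect_lte(hits$n_mismatch[i], 3L)
    expect_lte(hits$n_gap[i], 1L)
  }
})

test_that("off-target hits export to TSV and BED", {
  ps <- "ACGTTGCAGATCCGGATTCA"
  fx <- make_synthetic_genome(5000, plant_spec(ps, "TGG", copies_full = 2),
                              seed = 15)
  hits <- search_approximate(ps, fx$genome, alignment_budget(3, 1))
  txt <- offtargets_tsv(hits)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(length(lines), nrow(hits) + 1L)
  expect_true(startsWith(lines[1], "record_id\tstart\tend\tstrand"))
  bed <- tempfile(fileext = ".bed")
  offtargets_bed(hits, bed)
  back <- read_bed(bed)
  expect_equal(back$start, hits$start - 1L)  # BED is 0-based
  expect_equal(back$end, hits$end)
})

test_that("degenerate inputs error cleanly", {
  g <- genome_collection(c(r = random_dna(100)))
  expect_error(search_approximate("ACGTN" , g, alignment_budget()), "N")
  expect_error(search_approximate("A", g, alignment_budget()), "2-31")
  expect_error(alignment_budget(-1, 0))
})
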