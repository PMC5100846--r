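test_that("FASTA ingest parses valid entries and reports rejects with reasons", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ATGGCC",
               ">g2", "ATGGC",
               ">g3", "ATGNCCAAA"), path)
  parsed <- read_coding_fasta(path)
  expect_length(parsed$records, 1L)
  expect_equal(parsed$records[[1]]$gene_id, "g1")
  expect_equal(parsed$records[[1]]$seq, "ATGGCC")
  expect_setequal(parsed$rejects$gene_id, c("g2", "g3"))
  expect_equal(parsed$rejects$reason[parsed$rejects$gene_id == "g2"],
               "length not multiple of 3")
  expect_match(parsed$rejects$reason[parsed$rejects$gene_id == "g3"],
               "non-ACGT")
  expect_error(read_coding_fasta(file.path(tempdir(), "nope.fasta")),
               "cannot read")
})

test_that("coding sequences round-trip through write-then-read identically", {
  recs <- list(coding_sequence("a", "ATGGCCAAA"),
               coding_sequence("b", "GCGGCGTAA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_coding_fasta(recs, path)
  back <- read_coding_fasta(path)
  expect_equal(back$records, recs)
  expect_equal(nrow(back$rejects), 0L)
})

test_that("positional GC proportions match hand counts", {
  expect_equal(gc_by_codon_position(coding_sequence("x", "ATGGCCAAA"),
                                    include_terminal_stop = TRUE),
               c(gc1 = 1 / 3, gc2 = 1 / 3, gc3 = 2 / 3))
  expect_equal(gc_by_codon_position(coding_sequence("x", "GCGGCG")),
               c(gc1 = 1, gc2 = 1, gc3 = 1))
  # terminal stop excluded by default: only ATG counted
  expect_equal(gc_by_codon_position(coding_sequence("x", "ATGTAA")),
               c(gc1 = 0, gc2 = 0, gc3 = 1))
  # stop-only sequence leaves nothing to count
  expect_error(gc_by_codon_position(coding_sequence("x", "TAA")), "undefined")
})

test_that("positional GC sums to 3x overall GC for random sequences", {
  set.seed(11)
  for (i in 1:20) {
    cds <- random_cds(sample(10:200, 1))
    gc <- gc_by_codon_position(cds, include_terminal_stop = TRUE)
    overall <- mean(strsplit(cds$seq, "")[[1]] %in% c("G", "C"))
    expect_equal(sum(gc), 3 * overall, tolerance = 1e-12)
  }
})

test_that("relative adaptiveness normalizes within synonymous families", {
  counts <- setNames(numeric(61), sense_codons())
  counts["AAA"] <- 3; counts["AAG"] <- 1
  tab <- relative_adaptiveness(counts, pseudo_count = 0)
  expect_equal(unname(tab$w[c("AAA", "AAG")]), c(1, 1 / 3))
  # equal counts give weight 1 everywhere
  tab_eq <- relative_adaptiveness(setNames(rep(5, 61), sense_codons()),
                                  pseudo_count = 0)
  expect_true(all(tab_eq$w == 1))
  # zero-count family with a pseudo-count: equal weights of 1
  tab_ps <- relative_adaptiveness(counts * 0, pseudo_count = 0.5)
  expect_equal(unname(tab_ps$w[c("AAA", "AAG")]), c(1, 1))
  # max weight per family is always 1
  fam_max <- vapply(codon_families(), function(f) max(tab_ps$w[f]), numeric(1))
  expect_true(all(abs(fam_max - 1) < 1e-15))
  expect_error(relative_adaptiveness(setNames(c(-1), "AAA")), "non-negative")
  expect_error(relative_adaptiveness(setNames(1, "TAA")), "stop")
})

test_that("CAI matches the hand-computed geometric mean", {
  counts <- setNames(numeric(61), sense_codons())
  counts["AAA"] <- 3; counts["AAG"] <- 1
  tab <- relative_adaptiveness(counts, pseudo_count = 0.5)
  # w(AAA) = 1, w(AAG) = 1.5/3.5; but with pseudo_count 0 the classic case:
  tab0 <- relative_adaptiveness(counts, pseudo_count = 0)
  expect_equal(cai(coding_sequence("g", "AAAAAG"), tab0), sqrt(1 / 3))
  expect_error(cai(coding_sequence("g", "ATGTGG"), tab),
               "no countable codons")
})

test_that("a sequence of each family's most frequent codon has CAI 1", {
  set.seed(7)
  tab <- random_usage()
  best <- vapply(codon_families(), function(f) f[which.max(tab$w[f])],
                 character(1))
  best <- setdiff(best, c("ATG", "TGG"))
  cds <- coding_sequence("g", paste(best, collapse = ""))
  expect_equal(cai(cds, tab), 1)
})

test_that("CAI is invariant to codon permutation and matches the count oracle", {
  set.seed(21)
  tab <- random_usage()
  for (i in 1:25) {
    cds <- random_cds(sample(20:500, 1))
    perm <- coding_sequence("g", paste(sample(cds$codons), collapse = ""))
    expect_equal(cai(cds, tab), cai(perm, tab), tolerance = 1e-14)
    expect_equal(cai(cds, tab), cai_oracle(cds, tab), tolerance = 1e-12)
  }
})

test_that("CAI agrees with the seqinr reference implementation", {
  set.seed(31)
  tab <- random_usage()
  w64 <- setNames(numeric(64), tolower(seqinr::words()))
  w64[tolower(names(tab$w))] <- tab$w
  for (i in 1:5) {
    cds <- random_cds(200)
    ref <- as.numeric(seqinr::cai(tolower(seqinr::s2c(cds$seq)), w = w64))
    expect_equal(cai(cds, tab), ref, tolerance = 1e-10)
  }
})

test_that("nTE aggregation is the mean of per-codon weights", {
  nte_tab <- setNames(rep(0.8, 61), sense_codons())
  cds <- random_cds(30)
  expect_equal(nte_score(cds, nte_tab), 0.8)
  two <- coding_sequence("g", "AAAAAG")
  expect_equal(nte_score(two, c(AAA = 1.0, AAG = 0.5)), 0.75)
  expect_equal(nte_score(two, c(AAA = 1.0, AAG = 0.5), aggregate = "geometric"),
               sqrt(0.5))
  # mean bound property
  set.seed(5)
  nte_rand <- setNames(runif(61, 0.1, 2), sense_codons())
  for (i in 1:10) {
    cds <- random_cds(sample(5:100, 1))
    s <- nte_score(cds, nte_rand)
    w <- nte_rand[cds$codons]
    expect_gte(s, min(w)); expect_lte(s, max(w))
  }
  expect_error(nte_score(two, c(AAA = 1.0)), "AAG")
})

test_that("poly-proline classification requires an uninterrupted run", {
  pp <- function(codons) {
    polyproline_class(coding_sequence("g", paste(codons, collapse = "")))
  }
  expect_true(pp(c("ATG", "CCA", "CCG", "CCT", "CCC", "AAA")))
  expect_false(pp(c("CCA", "CCA", "CCA")))
  expect_false(pp(c("CCA", "CCA", "GCT", "CCA", "CCA")))
  expect_error(polyproline_class(coding_sequence("g", "CCA"), min_run = 0),
               "min_run")
  # monotonicity: extending an existing maximal run never flips true -> false
  base <- c("AAA", "CCA", "CCC", "CCG", "CCT", "GGG")
  expect_true(pp(base))
  expect_true(pp(append(base, "CCA", after = 2)))
})

test_that("the feature table covers all sequence-derived predictors", {
  set.seed(3)
  tab <- random_usage()
  nte_tab <- setNames(runif(61, 0.5, 1.5), sense_codons())
  recs <- list(random_cds(50, "g1"), random_cds(80, "g2"))
  feats <- sequence_feature_table(recs, tab, nte_tab)
  expect_equal(names(feats),
               c("gene_id", "coding_length", "gc1", "gc2", "gc3",
                 "cai", "nte", "polyproline"))
  expect_equal(feats$coding_length, c(150L, 240L))
  expect_true(all(feats$cai > 0 & feats$cai <= 1))
  expect_true(all(feats$gc1 >= 0 & feats$gc1 <= 1))
})
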