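# Expected Tm values frozen from an independent nearest-neighbor
# implementation (SantaLucia unified parameters, 50 mM monovalent salt,
# 250 nM primer, entropy salt correction).
TM_ORACLE <- c(
  "ATGCTGCCAGGAGTGTTCAATA" = 57.9058,
  "GCCTTCGTCTAATTCCTCTCTGAT" = 57.5163,
  "GCTCTATTTCTCTACCATTCTCACACT" = 57.5296,
  "CATTCAGCATCAACAATATCCTCCA" = 56.8617,
  "CCATTGGTAACAGCAAGTT" = 52.0278,
  "TAGTCTCTTCTCTGGCTATAC" = 51.1936,
  "GAAAGCCATAACTCGTTGATCTTGT" = 57.3078,
  "GCTCGCCACATAACAGGATACA" = 58.4087,
  "CTAAAGACAATTACATAACATAC" = 46.8592,
  "CGTCAGCACGAAACTTGT" = 54.8859,
  "GGCCCAGTGTGAATCGCTTAAGGGT" = 64.3857,
  "AAGTAAGTGTGATGCATACGCCTTT" = 58.7151,
  "CTTGCTGTGTCCACCCCAT" = 58.4800,
  "GGACTGGCATTTTTATTACA" = 49.7416,
  "TCAGAAACAGAACTCGGGTAA" = 54.7225,
  "TTTGACAGGTCACGCAGAGGCGCGC" = 69.2184,
  "CTCCTGAAGTGCGTGGACACT" = 60.4157,
  "GCTATGAATCTCTGATTTACC" = 49.7160,
  "ACTCTGCCAAACTCCAGCGC" = 61.6882,
  "GTCAGTTCCATCACCCTAAGTAA" = 55.3010)

test_that("nearest-neighbor Tm agrees with the independent oracle within 1 degree", {
  for (s in names(TM_ORACLE)) {
    expect_lt(abs(tm_nn(s) - TM_ORACLE[[s]]), 1, label = s)
  }
  expect_error(tm_nn("ACGTX"), "A/C/G/T")
})

test_that("primer pairs carry Tms and a correctly prepended 18 bp M13 tail", {
  p <- primer_pair("M1", "GCTCGCCACATAACAGGATACA",
                   "GAAAGCCATAACTCGTTGATCTTGT", 129L, dye = "FAM")
  expect_s3_class(p, "PrimerPair")
  expect_equal(nchar(p$m13_tagged_forward), nchar(p$forward_seq) + 18L)
  expect_equal(substr(p$m13_tagged_forward, 19, nchar(p$m13_tagged_forward)),
               p$forward_seq)
  expect_equal(p$tm_forward, tm_nn(p$forward_seq))
  expect_error(primer_pair("M", "", "ACGT", 100L), "non-empty")
  expect_error(primer_pair("M", "ACGU", "ACGT", 100L), "ACGT")
})

test_that("amplicon-size criterion passes the published range and fails outside it", {
  p209 <- primer_pair("LSSR-4", "GCCTTCGTCTAATTCCTCTCTGAT",
                      "ATGCTGCCAGGAGTGTTCAATA", 209L)
  ev <- evaluate_primer_pair(p209)
  expect_true(ev$criteria[["amplicon_size"]])

  p320 <- primer_pair("X", "GCCTTCGTCTAATTCCTCTCTGAT",
                      "ATGCTGCCAGGAGTGTTCAATA", 320L)
  expect_false(evaluate_primer_pair(p320)$criteria[["amplicon_size"]])
  # boundary: 300 passes, 49 fails
  p300 <- primer_pair("X", "GCCTTCGTCTAATTCCTCTCTGAT",
                      "ATGCTGCCAGGAGTGTTCAATA", 300L)
  expect_true(evaluate_primer_pair(p300)$criteria[["amplicon_size"]])
  p49 <- primer_pair("X", "GCCTTCGTCTAATTCCTCTCTGAT",
                     "ATGCTGCCAGGAGTGTTCAATA", 49L)
  expect_false(evaluate_primer_pair(p49)$criteria[["amplicon_size"]])
})

test_that("a fully self-complementary pair fails the dimer check at full length", {
  f <- "GCTCGCCACATAACAGGATACA"
  p <- primer_pair("X", f, reverse_complement(f), 100L)
  runs <- primer_dimer_runs(p$forward_seq, p$reverse_seq)
  expect_equal(runs$max_run, nchar(f))
  expect_false(evaluate_primer_pair(p)$criteria[["no_dimer"]])
})

test_that("3'-anchored complementarity is held to the stricter limit", {
  f <- "GCTCGCCACATAACAGGATACA"
  # reverse primer whose 3' end is complementary to the forward 3' end
  r <- paste0("TTCCGGAATC", reverse_complement(substr(f, 17, 22)))
  runs <- primer_dimer_runs(f, r)
  expect_gte(runs$max_run_3prime, 5L)
  p <- primer_pair("X", f, r, 100L)
  expect_false(evaluate_primer_pair(p)$criteria[["no_dimer"]])
})

test_that("criteria are evaluated independently on a constructed locus", {
  set.seed(77)
  left <- random_dna(300); right <- random_dna(300)
  core <- strrep("GCA", 7)
  g <- genome_sequence(c(chr1 = paste0(random_dna(400), left, core,
                                       right, random_dna(400))), "G1")
  loci <- detect_ssrs(g)
  fl <- extract_flanked(loci, g, 300L)
  forward <- substr(left, 251, 272)
  reverse <- reverse_complement(substr(right, 31, 52))
  p <- primer_pair("M", forward, reverse, 0L)
  ev <- evaluate_primer_pair(p, flanked = fl[1, ], genomes = list(g))
  expect_true(ev$criteria[["in_flanks"]])
  expect_equal(ev$amplicon_len, 50L + 21L + 52L)
  expect_true(ev$criteria[["specific"]])
  expect_true(ev$criteria[["m13_tagged"]])

  # a primer overlapping the core is not in the conserved flanks
  p_bad <- primer_pair("M", paste0(substr(left, 290, 300),
                                   substr(core, 1, 11)),
                       reverse, 100L)
  ev_bad <- evaluate_primer_pair(p_bad, flanked = fl[1, ],
                                 genomes = list(g))
  expect_false(ev_bad$criteria[["in_flanks"]])

  # a duplicated priming site breaks specificity only
  g_dup <- genome_sequence(c(chr1 = paste0(
    random_dna(200), left, core, right,
    random_dna(100), left, core, right, random_dna(200))), "G2")
  ev_dup <- evaluate_primer_pair(p, flanked = fl[1, ],
                                 genomes = list(g_dup))
  expect_false(ev_dup$criteria[["specific"]])
  expect_true(ev_dup$criteria[["amplicon_size"]])
})

test_that("published pairs all carry similar annealing temperatures", {
  tab <- utils::read.delim(system.file("extdata",
                                       "jujube_primer_panel.tsv",
                                       package = "mgbssr"))
  dts <- vapply(seq_len(nrow(tab)), function(i) {
    p <- primer_pair(tab$marker[i], tab$forward[i], tab$reverse[i],
                     tab$expected_len[i], dye = tab$dye[i])
    abs(p$tm_forward - p$tm_reverse)
  }, numeric(1))
  expect_true(all(dts <= 8))  # panel designed for one annealing program
})

test_that("panel packing is deterministic and respects separation and capacity", {
  mk <- function(id, len) {
    primer_pair(id, "GCTCGCCACATAACAGGATACA",
                "GAAAGCCATAACTCGTTGATCTTGT", len)
  }
  lens <- seq(100L, 320L, by = 20L)  # 12 pairs, exactly packable
  pairs <- Map(mk, sprintf("M%02d", seq_along(lens)), lens)
  pan <- assign_panels(pairs, per_panel = 3L)
  expect_equal(nrow(pan), 12L)
  expect_equal(unname(table(pan$dye)), rep(3L, 4L) , ignore_attr = TRUE)
  for (d in unique(pan$dye)) {
    l <- sort(pan$expected_amplicon_len[pan$dye == d])
    expect_true(all(diff(l) >= 20L))
  }
  expect_identical(assign_panels(pairs, per_panel = 3L), pan)

  expect_equal(assign_panels(list(mk("A", 150L)))$dye, "FAM")
  expect_error(assign_panels(list(mk("A", 150L), mk("B", 150L)),
                             dyes = "FAM", per_panel = 2L),
               "cannot pack")
  expect_error(assign_panels(pairs, dyes = "FAM", per_panel = 3L),
               "capacity")
})
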