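make_flanked_genome <- function(left, motif, count, right,
                                pad = 500L, seed = 1) {
  set.seed(seed)
  s <- paste0(random_dna(pad), left, strrep(motif, count), right,
              random_dna(pad))
  genome_sequence(c(chr1 = s), "tgt")
}

test_that("flank extraction yields exact genome substrings, truncated at edges", {
  set.seed(2)
  s <- paste0(random_dna(500), strrep("GCA", 7), random_dna(1500))
  g <- genome_sequence(c(chr1 = s), "t")
  loci <- detect_ssrs(g)
  fl <- extract_flanked(loci, g, 300L)
  expect_equal(nchar(fl$left_flank), 300L)
  expect_equal(nchar(fl$right_flank), 300L)
  expect_false(fl$truncated)
  expect_equal(fl$full_seq,
               subsequence(g, "chr1", fl$start - 300L, fl$end + 300L))

  s2 <- paste0(substr(random_dna(10), 1, 10), strrep("GCA", 7),
               random_dna(400))
  g2 <- genome_sequence(c(chr1 = s2), "t")
  fl2 <- extract_flanked(detect_ssrs(g2), g2, 300L)
  expect_equal(nchar(fl2$left_flank), 10L)
  expect_true(fl2$truncated)

  fl0 <- extract_flanked(loci, g, 0L)
  expect_equal(fl0$full_seq, fl0$core_seq)
})

test_that("search finds exact substrings at identity 1 on either strand", {
  set.seed(8)
  g <- genome_sequence(c(chr1 = random_dna(3000)), "t")
  q <- subsequence(g, "chr1", 1000, 1080)
  h <- search_genome(q, g)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 1000L)
  expect_equal(h$flank_identity, 1)

  hrc <- search_genome(reverse_complement(q), g)
  expect_equal(nrow(hrc), 1L)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$start, 1000L)

  expect_error(search_genome("ACGTACG", g), "seed")
})

test_that("flank identity excises the core and is filtered at the threshold", {
  left <- local({set.seed(31); random_dna(300)})
  right <- local({set.seed(32); random_dna(300)})
  motif <- "GCA"
  query <- paste0(left, strrep(motif, 7), right)
  core <- c(300L, 321L)

  mutate_n <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    for (p in sample(nchar(s), k)) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }

  # target carries a different repeat count: identity must stay 1.0
  g_same <- make_flanked_genome(left, motif, 11, right, seed = 41)
  h <- search_genome(query, g_same, core = core, motif = motif)
  expect_equal(h$flank_identity, 1)
  expect_equal(h$target_repeat_count, 11L)

  # 5% flank substitutions: retained above the 0.90 threshold
  g_5 <- make_flanked_genome(mutate_n(left, 15, 51), motif, 9,
                             mutate_n(right, 15, 52), seed = 42)
  h5 <- search_genome(query, g_5, core = core, motif = motif)
  expect_equal(nrow(h5), 1L)
  expect_gte(h5$flank_identity, 0.90)

  # 15% substitutions: no qualifying hit at min_identity 0.90
  g_15 <- make_flanked_genome(mutate_n(left, 45, 53), motif, 9,
                              mutate_n(right, 45, 54), seed = 43)
  h15 <- search_genome(query, g_15, core = core, motif = motif)
  expect_equal(nrow(h15), 0L)
})

test_that("matched-site repeat counts are recomputed, not inferred from length", {
  left <- local({set.seed(61); random_dna(300)})
  right <- local({set.seed(62); random_dna(300)})
  query <- paste0(left, strrep("TTAG", 5), right)
  g <- make_flanked_genome(left, "TTAG", 9, right, seed = 63)
  h <- search_genome(query, g, core = c(300L, 320L), motif = "TTAG")
  expect_equal(h$target_repeat_count, 9L)
  expect_equal(h$core_gap, 36L)
})

test_that("screen classifies every planted class correctly on a small trio", {
  spec <- plant_spec(n_per_class = c(three_way_polymorphic = 3L,
                                     two_way_only = 3L, monomorphic = 3L,
                                     nonunique_decoy = 3L,
                                     low_identity_flank = 3L,
                                     flank_mutation = 3L),
                     spacer_len = 400L)
  sim <- generate_genomes(spec, 3, seed = 17)
  scr <- screen_polymorphic(sim$genomes)
  m <- merge(sim$truth, scr$loci, by.x = "start_G1", by.y = "start")
  expect_equal(nrow(m), 18L)
  expect_equal(m$status, unname(expected_status[m$class]))
  # retained loci report the planted per-genome repeat counts
  r <- m[m$status == "retained", ]
  expect_equal(r$rc_G1.y, r$rc_G1.x)
  expect_equal(r$rc_G2.y, r$rc_G2.x)
  expect_equal(r$rc_G3.y, r$rc_G3.x)
})

test_that("the candidate funnel is non-increasing", {
  spec <- plant_spec(n_per_class = c(three_way_polymorphic = 2L,
                                     monomorphic = 2L,
                                     nonunique_decoy = 2L),
                     spacer_len = 400L)
  sim <- generate_genomes(spec, 3, seed = 5)
  scr <- screen_polymorphic(sim$genomes)
  expect_true(all(diff(scr$funnel) <= 0))
  expect_equal(unname(scr$funnel["detected"]), 6L)
  expect_equal(unname(scr$funnel["retained"]), 2L)
})

test_that("raising min_identity or adding a genome never grows the retained set", {
  spec <- plant_spec(n_per_class = c(three_way_polymorphic = 3L,
                                     low_identity_flank = 3L,
                                     flank_mutation = 2L),
                     spacer_len = 400L)
  sim4 <- generate_genomes(spec, 4, seed = 29)
  g3 <- sim4$genomes[1:3]
  ret <- function(gs, mi) {
    screen_polymorphic(gs, min_identity = mi)$retained$locus_id
  }
  r_90 <- ret(g3, 0.90)
  r_97 <- ret(g3, 0.97)
  expect_true(all(r_97 %in% r_90))
  r4 <- ret(sim4$genomes, 0.90)
  expect_true(all(r4 %in% r_90))
})

test_that("with two genomes the all-genomes stage degenerates to a no-op", {
  spec <- plant_spec(n_per_class = c(two_way_only = 3L, monomorphic = 3L),
                     spacer_len = 400L)
  sim <- generate_genomes(spec, 2, seed = 11)
  scr <- screen_polymorphic(sim$genomes)
  m <- merge(sim$truth, scr$loci, by.x = "start_G1", by.y = "start")
  expect_equal(m$status[m$class == "two_way_only"], rep("retained", 3))
  expect_equal(m$status[m$class == "monomorphic"],
               rep("dropped_monomorphic", 3))
  expect_error(screen_polymorphic(sim$genomes[1]), "at least 2")
  expect_error(screen_polymorphic(sim$genomes, anchor = "nope"),
               "anchor")
})
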