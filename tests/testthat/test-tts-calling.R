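# One TU on a 600 bp chromosome; counts are poked into both replicate
# tracks at chosen -1/+1 sites inside the 200 nt search window.
criteria_fixture <- function(counts_rep1, counts_rep2, pos = 350L,
                             strand = "+") {
  genome <- toy_genome(c(chr = paste(rep("A", 600), collapse = "")))
  if (strand == "+") {
    tu <- make_tu("tu1", "chr", "+", 100, 420, stop_codon_end = 300)
    p1 <- pos + 1L
  } else {
    tu <- make_tu("tu1", "chr", "-", 180, 500, stop_codon_end = 300)
    p1 <- pos - 1L
  }
  t1 <- poke(make_track(genome), "chr", strand, c(pos, p1), counts_rep1)
  t2 <- poke(make_track(genome), "chr", strand, c(pos, p1), counts_rep2)
  list(tracks = list(t1, t2), tus = tu, pos = pos)
}

test_that("the ratio and difference criteria decide candidacy exactly", {
  # 12 vs 5: ratio 2.4 > 1.1 and diff 7 > 5 in both replicates -> called
  fx <- criteria_fixture(c(12, 5), c(12, 5))
  calls <- call_primary_tts(fx$tracks, fx$tus)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tts_pos, fx$pos)
  expect_equal(calls$score, 14)
  expect_equal(calls$ratio_rep1, 2.4)

  # 6 vs 5: ratio passes but difference 1 <= 5 -> no call
  fx <- criteria_fixture(c(6, 5), c(6, 5))
  expect_equal(nrow(call_primary_tts(fx$tracks, fx$tus)), 0L)

  # passing in replicate 1 only is not enough
  fx <- criteria_fixture(c(12, 5), c(6, 5))
  expect_equal(nrow(call_primary_tts(fx$tracks, fx$tus)), 0L)

  # a +1 count of zero gives an infinite ratio but still needs diff > 5
  fx <- criteria_fixture(c(6, 0), c(6, 0))
  calls <- call_primary_tts(fx$tracks, fx$tus)
  expect_equal(nrow(calls), 1L)
  fx <- criteria_fixture(c(4, 0), c(4, 0))
  expect_equal(nrow(call_primary_tts(fx$tracks, fx$tus)), 0L)
})

test_that("TTS calling works identically on the minus strand", {
  fx <- criteria_fixture(c(20, 3), c(15, 4), pos = 250L, strand = "-")
  calls <- call_primary_tts(fx$tracks, fx$tus)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tts_pos, 250L)
  expect_equal(calls$strand, "-")
  expect_equal(calls$dist_to_stop, 50L)
})

test_that("score ties break toward the stop codon", {
  genome <- toy_genome(c(chr = paste(rep("A", 600), collapse = "")))
  tu <- make_tu("tu1", "chr", "+", 100, 520, stop_codon_end = 300)
  mk <- function() {
    tr <- make_track(genome)
    # two candidates with identical evidence at 340 and 380
    poke(tr, "chr", "+", c(340L, 341L, 380L, 381L), c(20, 2, 20, 2))
  }
  calls <- call_primary_tts(list(mk(), mk()), tu)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tts_pos, 340L)
})

test_that("fewer than two replicates is an error and the window respects contig ends", {
  genome <- toy_genome(c(chr = paste(rep("A", 400), collapse = "")))
  tu <- make_tu("tu1", "chr", "+", 100, 395, stop_codon_end = 300)
  tr <- poke(make_track(genome), "chr", "+", c(350L, 351L), c(30, 2))
  expect_error(call_primary_tts(list(tr), tu), "2 replicate")
  calls <- call_primary_tts(list(tr, tr), tu)
  expect_true(calls$truncated)
  expect_equal(calls$tts_pos, 350L)
})

test_that("relaxing the difference threshold never removes calls", {
  cfg <- sim_config(seed = 31, n_tus = 40)
  sim <- simulate_genome(cfg)
  t1 <- simulate_termseq(sim$genome, sim$tus, sim$truth, "dep", 1, cfg)
  t2 <- simulate_termseq(sim$genome, sim$tus, sim$truth, "dep", 2, cfg)
  strict <- call_primary_tts(list(t1, t2), sim$tus, diff_min = 5)
  loose <- call_primary_tts(list(t1, t2), sim$tus, diff_min = 0)
  expect_true(all(strict$tu_id %in% loose$tu_id))
})

test_that("uniform scaling preserves the ratio criterion but not the difference criterion", {
  scale_track <- function(tr, c) {
    for (chrom in names(tr$values)) for (s in c("+", "-")) {
      tr$values[[chrom]][[s]] <- tr$values[[chrom]][[s]] * c
    }
    tr
  }
  # the ratio is scale-free: scaling both replicates leaves it unchanged
  fx <- criteria_fixture(c(40, 30), c(40, 30))
  base <- call_primary_tts(fx$tracks, fx$tus, diff_min = 0.5)
  scaled <- call_primary_tts(lapply(fx$tracks, scale_track, c = 10),
                             fx$tus, diff_min = 0.5)
  expect_equal(scaled$ratio_rep1, base$ratio_rep1)
  expect_equal(nrow(base), nrow(scaled))

  # diff-limited case: 8 vs 4 fails diff (4 <= 5) but passes once scaled x3
  fx <- criteria_fixture(c(8, 4), c(8, 4))
  expect_equal(nrow(call_primary_tts(fx$tracks, fx$tus)), 0L)
  calls <- call_primary_tts(lapply(fx$tracks, scale_track, c = 3), fx$tus)
  expect_equal(nrow(calls), 1L)
})

test_that("the terminator PFM is one-hot for a single call and strand-aware", {
  genome <- toy_genome(c(chr = "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"))
  call_plus <- tibble::tibble(tu_id = "a", chrom = "chr", strand = "+",
                              tts_pos = 40L)
  pfm <- extract_terminator_pfm(call_plus, genome, upstream = 5, downstream = 3)
  expect_equal(pfm$n_sequences, 1L)
  expect_true(all(colSums(pfm$counts) == 1L))
  seq_fwd <- as.character(Biostrings::subseq(genome[["chr"]], 37, 44))
  rebuilt <- paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)],
                   collapse = "")
  expect_equal(rebuilt, seq_fwd)

  call_minus <- tibble::tibble(tu_id = "b", chrom = "chr", strand = "-",
                               tts_pos = 20L)
  pfm_m <- extract_terminator_pfm(call_minus, genome, upstream = 5, downstream = 3)
  expected <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[["chr"]], 18, 25)))
  rebuilt_m <- paste(rownames(pfm_m$counts)[apply(pfm_m$counts, 2, which.max)],
                     collapse = "")
  expect_equal(rebuilt_m, expected)
})

test_that("PFM columns always sum to the number of used sequences", {
  cfg <- sim_config(seed = 8, n_tus = 40)
  sim <- simulate_genome(cfg)
  calls <- tibble::tibble(tu_id = sim$truth$tu_id, chrom = "chrSim",
                          strand = sim$truth$strand,
                          tts_pos = sim$truth$true_tts)
  pfm <- extract_terminator_pfm(calls, sim$genome)
  expect_true(all(colSums(pfm$counts) == pfm$n_sequences))
  expect_equal(pfm$n_sequences + pfm$n_excluded, nrow(calls))
  # planted tracts: T fraction at the last u_min positions before the TTS
  u_min <- min(sim$truth$u_len)
  sel <- pfm$positions %in% (-u_min):(-1)
  expect_true(all(pfm$t_fraction[sel] >= 0.95))
})

test_that("metaplot normalization anchors position -21 at exactly 1", {
  genome <- toy_genome(c(chr = paste(rep("A", 400), collapse = "")))
  calls <- tibble::tibble(tu_id = "a", chrom = "chr", strand = "+",
                          tts_pos = 200L)
  flat <- make_track(genome)
  flat <- termseqr:::set_track_values(flat, "chr", "+", rep(10, 400))
  prof <- metaplot(flat, calls)
  expect_equal(nrow(prof), 41L)
  expect_false(0 %in% prof$position)
  expect_equal(prof$normalized, rep(1, 41))
  expect_equal(tts_decrease(prof), 0)

  step <- make_track(genome)
  step <- termseqr:::set_track_values(step, "chr", "+",
                                      c(rep(10, 201), rep(0, 199)))
  prof_step <- metaplot(step, calls)
  expect_equal(prof_step$normalized[prof_step$position < 0], rep(1, 21))
  expect_equal(prof_step$normalized[prof_step$position > 0], rep(0, 20))
  expect_equal(tts_decrease(prof_step), 1)

  empty <- make_track(genome)
  expect_error(metaplot(empty, calls), "-21")
})

test_that("the -2/+2 decrease follows its definition, including read-through", {
  prof <- tibble::tibble(position = c(seq(-21, -1), seq(1, 20)),
                         mean_raw = 1, normalized = 1)
  prof$normalized[prof$position == -2] <- 1.0
  prof$normalized[prof$position == 2] <- 0.4
  expect_equal(tts_decrease(prof), 0.6)
  prof$normalized[prof$position == 2] <- 1.5
  expect_equal(tts_decrease(prof), -0.5)
  prof$normalized[prof$position == -2] <- 0
  expect_error(tts_decrease(prof), "-2")
})

test_that("TTS recovery on efficient synthetic termination is near-perfect", {
  cfg <- sim_config(seed = 12, n_tus = 60)
  sim <- simulate_genome(cfg)
  t1 <- simulate_termseq(sim$genome, sim$tus, sim$truth, "wt", 1, cfg)
  t2 <- simulate_termseq(sim$genome, sim$tus, sim$truth, "wt", 2, cfg)
  calls <- call_primary_tts(list(t1, t2), sim$tus)
  hit <- abs(calls$tts_pos[match(sim$truth$tu_id, calls$tu_id)] -
               sim$truth$true_tts) <= 1
  expect_gte(mean(hit, na.rm = TRUE) * mean(!is.na(hit)), 0.95)
})
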