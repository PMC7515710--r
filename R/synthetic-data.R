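#' Configuration for the synthetic termination dataset
#'
#' Bundles every knob of the generator with defaults that describe the
#' study conditions the rest of the package is tested under: a compact
#' prokaryote-like genome of tandem/convergent TUs, U-rich intrinsic
#' terminators planted at the true TTSs, efficient termination in the
#' wild type (`eff` 0.9) versus leaky termination under terminator-factor
#' depletion (`eff` 0.3), and condition-dependent read-through of
#' coverage into intergenic regions (fractions 0.12 vs 0.40 of body
#' coverage, with a 1.2-fold body change), giving a configured IGR fold
#' change of 4.0 against a TU-body fold of 1.2.
#'
#' @param seed master integer seed; every random draw in the generator
#'   is a deterministic function of it (one derived stream per
#'   condition/replicate/track so adding replicates never perturbs
#'   existing tracks).
#' @param n_tus number of transcription units.
#' @param chrom_length chromosome length in bp, or `NULL` to size the
#'   chromosome to fit the requested TUs. An explicit length too short
#'   for the layout is an error.
#' @param tu_length_range,igr_length_range min/max TU length and
#'   inter-TU gap in bp.
#' @param utr_length_range min/max distance (nt) from the stop codon to
#'   the true TTS; kept within the 200 nt search window by default.
#' @param u_tract_length_range min/max length of the planted terminal
#'   T-tract (U in RNA).
#' @param expression_sdlog log-normal sdlog of relative TU abundance.
#' @param termination_efficiency named numeric, probability that a
#'   transcript 3'-end falls exactly on the true TTS, per condition.
#' @param readthrough_decay geometric parameter p in (0,1) for the
#'   post-TTS 3'-end tail (downstream base d has weight (1-p) p^(d-1)).
#' @param tts_jitter numeric vector of probabilities for terminated
#'   3'-ends to fall 2 nt upstream, 1 nt upstream, or exactly on the
#'   true TTS (termination is positionally imprecise; the primary site
#'   keeps the majority of the signal).
#' @param readthrough_fraction named numeric, IGR coverage as a fraction
#'   of body coverage immediately downstream of the TTS, per condition.
#' @param body_fold_dep multiplicative change of body coverage in the
#'   depleted condition relative to wild type.
#' @param depth expected total 3'-end reads per condition per replicate.
#' @param coverage_depth mean wild-type body coverage (x-fold).
#' @param coverage_decay_bp exponential length scale of the coverage
#'   read-through tail.
#' @param background expected uniform 3'-end counts per base (noise
#'   floor exercising the absolute count threshold of TTS calling).
#' @param replicates replicates per condition.
#' @param read_length nominal read length used to convert coverage sums
#'   to fragment counts.
#' @param tail_cutoff maximal extent (nt) of the 3'-end geometric tail.
#' @param strand_prob probability that a TU is placed on the plus
#'   strand (0.5 mixes tandem and convergent neighbours).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tus = 200L,
                       chrom_length = NULL,
                       tu_length_range = c(600L, 1200L),
                       igr_length_range = c(150L, 300L),
                       utr_length_range = c(20L, 150L),
                       u_tract_length_range = c(5L, 8L),
                       expression_sdlog = 0.5,
                       termination_efficiency = c(wt = 0.9, dep = 0.3),
                       readthrough_decay = 0.85,
                       tts_jitter = c(0.10, 0.20, 0.70),
                       readthrough_fraction = c(wt = 0.12, dep = 0.40),
                       body_fold_dep = 1.2,
                       depth = 100 * n_tus,
                       coverage_depth = 50,
                       coverage_decay_bp = 600,
                       background = 0.05,
                       replicates = 2L,
                       read_length = 150L,
                       tail_cutoff = 200L,
                       strand_prob = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_tus = as.integer(n_tus),
    chrom_length = chrom_length,
    tu_length_range = as.integer(tu_length_range),
    igr_length_range = as.integer(igr_length_range),
    utr_length_range = as.integer(utr_length_range),
    u_tract_length_range = as.integer(u_tract_length_range),
    expression_sdlog = expression_sdlog,
    termination_efficiency = termination_efficiency,
    readthrough_decay = readthrough_decay,
    tts_jitter = tts_jitter,
    readthrough_fraction = readthrough_fraction,
    body_fold_dep = body_fold_dep,
    depth = depth, coverage_depth = coverage_depth,
    coverage_decay_bp = coverage_decay_bp,
    background = background, replicates = as.integer(replicates),
    read_length = as.integer(read_length),
    tail_cutoff = as.integer(tail_cutoff),
    strand_prob = strand_prob
  )
  if (cfg$n_tus < 1) abort("n_tus must be >= 1")
  probs <- c(cfg$termination_efficiency, cfg$readthrough_decay,
             cfg$readthrough_fraction, cfg$strand_prob)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (length(cfg$tts_jitter) != 3 || any(cfg$tts_jitter < 0) ||
      abs(sum(cfg$tts_jitter) - 1) > 1e-9) {
    abort("tts_jitter must be 3 probabilities (offsets -2, -1, 0) summing to 1")
  }
  if (any(c(cfg$tu_length_range, cfg$igr_length_range,
            cfg$u_tract_length_range) < 1)) {
    abort("length ranges must be positive")
  }
  for (nm in c("termination_efficiency", "readthrough_fraction")) {
    if (!all(c("wt", "dep") %in% names(cfg[[nm]]))) {
      abort(sprintf("%s must be named with conditions 'wt' and 'dep'", nm))
    }
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-stream seed: one RNG stream per
# (condition, replicate, track kind), derived from the master seed so
# streams are independent of the order tracks are generated in.
stream_seed <- function(seed, condition, replicate, kind) {
  h <- sum(utf8ToInt(paste(condition, kind, sep = "/")))
  as.integer((as.numeric(seed) * 48271 + h * 7919 +
                as.numeric(replicate) * 104729) %% 2147483647)
}

sample_int_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(range[1]:range[2], n, replace = TRUE)
}

#' Simulate a genome with planted U-rich terminators
#'
#' Lays `n_tus` transcription units along one random-sequence
#' chromosome, each assigned a strand at random, separated by gaps drawn
#' from `igr_length_range`. Each TU carries, in transcription sense, a
#' stop codon (TAA) followed by a 3' UTR whose final `u` bases are a
#' planted T-tract (U in the transcript) ending exactly at the true TTS,
#' which coincides with the TU's 3' boundary. True TTSs therefore lie at
#' most 200 nt downstream of the stop codon under the default UTR range.
#'
#' @param config a [sim_config()].
#' @return a list with `genome` (a `DNAStringSet`, one chromosome
#'   `"chrSim"`), `tus` (TU tibble; `tts` left `NA` so callers exercise
#'   TTS calling), and `truth` (tibble: `tu_id`, `strand`, `true_tts`,
#'   `u_len`, `dist_to_stop`, `eff_wt`, `eff_dep`, `rt_wt`, `rt_dep`,
#'   `abundance`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "genome", 0, "layout"))
  n <- config$n_tus
  tu_len <- sample_int_range(n, config$tu_length_range)
  gaps <- sample_int_range(n + 1, config$igr_length_range)
  u_len <- sample_int_range(n, config$u_tract_length_range)
  utr_min <- pmax(config$utr_length_range[1], u_len + 4L)
  utr <- utr_min +
    floor(runif(n) * pmax(1L, config$utr_length_range[2] - utr_min + 1L))
  strand <- ifelse(runif(n) < config$strand_prob, "+", "-")
  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = config$expression_sdlog)

  starts <- integer(n)
  pos <- gaps[1]
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + tu_len[i] + gaps[i + 1]
  }
  needed <- pos
  chrom_length <- config$chrom_length %||% needed
  if (chrom_length < needed) {
    abort(sprintf(
      "chrom_length %d too short for %d TUs (need %d bp)",
      chrom_length, n, needed
    ))
  }
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)

  ends <- starts + tu_len
  tts <- ifelse(strand == "+", ends - 1L, starts)
  stop_codon_end <- as.integer(downstream_pos(tts, strand, -utr))
  for (i in seq_len(n)) {
    # sense 3' cassette: stop codon, UTR, terminal T-tract ending at TTS
    cassette <- c("T", "A", "A",
                  sample(c("A", "C", "G"), utr[i] - u_len[i], replace = TRUE),
                  rep("T", u_len[i]))
    if (strand[i] == "+") {
      idx <- (stop_codon_end[i] - 2L):tts[i]
      seq_chars[idx + 1L] <- cassette
    } else {
      idx <- (stop_codon_end[i] + 2L):tts[i] # decreasing forward axis
      seq_chars[idx + 1L] <- chartr("ACGT", "TGCA", cassette)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chrSim"

  tus <- tibble(
    tu_id = sprintf("TU%04d", seq_len(n)),
    chrom = "chrSim", strand = strand,
    start = starts, end = ends,
    tss = ifelse(strand == "+", starts, ends - 1L),
    stop_codon_end = stop_codon_end,
    tts = NA_integer_,
    is_noncoding = FALSE
  )
  validate_tus(tus)
  truth <- tibble(
    tu_id = tus$tu_id, strand = strand,
    true_tts = as.integer(tts), u_len = u_len,
    dist_to_stop = as.integer(utr),
    eff_wt = unname(config$termination_efficiency["wt"]),
    eff_dep = unname(config$termination_efficiency["dep"]),
    rt_wt = unname(config$readthrough_fraction["wt"]),
    rt_dep = unname(config$readthrough_fraction["dep"]),
    abundance = abundance
  )
  list(genome = genome, tus = tus, truth = truth)
}

#' Simulate a Term-seq 3'-end count track
#'
#' For each TU with expected read budget `lambda = depth x abundance
#' share`, draws Poisson counts totalling `lambda x eff` in expectation
#' at the true TTS and the 1-2 nt immediately upstream (split by
#' `tts_jitter`, emulating the positional imprecision of termination,
#' with the majority on the primary site), a geometric read-through tail
#' `lambda x (1 - eff) x (1-p) p^(d-1)` at each downstream base `d`,
#' plus a uniform Poisson background on both strands. Each (condition,
#' replicate) pair has its own RNG stream derived from the master seed.
#'
#' @param genome,tus,truth from [simulate_genome()].
#' @param condition `"wt"` or `"dep"`.
#' @param replicate replicate number (1-based).
#' @param config the same [sim_config()].
#' @return a `stranded_track` of kind `"three_prime_end"`.
#' @export
simulate_termseq <- function(genome, tus, truth, condition, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, condition, replicate, "termseq"))
  lengths <- genome_lengths(genome)
  track <- stranded_track(lengths, kind = "three_prime_end",
                          label = sprintf("%s_rep%d", condition, replicate))
  eff_col <- if (condition == "wt") "eff_wt" else "eff_dep"
  share <- truth$abundance / sum(truth$abundance)
  lambda <- config$depth * share
  p <- config$readthrough_decay
  d <- seq_len(config$tail_cutoff)
  tail_w <- (1 - p) * p^(d - 1)

  for (i in seq_len(nrow(truth))) {
    chrom <- tus$chrom[i]
    strand <- truth$strand[i]
    len <- lengths[[chrom]]
    v <- track$values[[chrom]][[strand]]
    eff <- truth[[eff_col]][i]
    tts <- truth$true_tts[i]
    peak_pos <- downstream_pos(tts, strand, c(-2L, -1L, 0L))
    peak_ok <- peak_pos >= 0 & peak_pos < len
    peak_counts <- rpois(sum(peak_ok),
                         lambda[i] * eff * config$tts_jitter[peak_ok])
    v[peak_pos[peak_ok] + 1L] <- v[peak_pos[peak_ok] + 1L] + peak_counts
    tail_pos <- downstream_pos(tts, strand, d)
    ok <- tail_pos >= 0 & tail_pos < len
    counts <- rpois(sum(ok), lambda[i] * (1 - eff) * tail_w[ok])
    idx <- tail_pos[ok] + 1L
    v[idx] <- v[idx] + counts
    track$values[[chrom]][[strand]] <- v
  }
  if (config$background > 0) {
    for (chrom in names(lengths)) {
      for (s in c("+", "-")) {
        track$values[[chrom]][[s]] <- track$values[[chrom]][[s]] +
          rpois(lengths[[chrom]], config$background)
      }
    }
  }
  track
}

#' Simulate a strand-specific coverage track
#'
#' Per-base coverage is Poisson around a body level over the TU
#' ([TSS, TTS] in transcription sense) and, downstream of the TTS,
#' around `body x readthrough_fraction(condition) x exp(-d / decay)`,
#' emulating condition-dependent read-through of polymerases past the
#' terminator into the intergenic region (and, when the tail is long,
#' into the next TU on the same strand). The depleted condition also
#' scales the body by `body_fold_dep`.
#'
#' A stable-RNA ballast block (the un-annotated region upstream of the
#' first TU, standing in for the rRNA fraction that dominates real
#' libraries) is filled per condition so that both conditions have the
#' same expected total signal: per-million FPKM normalization then
#' leaves the configured body and IGR fold changes intact, as it does in
#' depth-matched sequencing libraries.
#'
#' @inheritParams simulate_termseq
#' @return a `stranded_track` of kind `"coverage"`.
#' @export
simulate_coverage <- function(genome, tus, truth, condition, config,
                              replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, condition, replicate, "coverage"))
  lengths <- genome_lengths(genome)
  track <- stranded_track(lengths, kind = "coverage",
                          label = sprintf("%s_cov%d", condition, replicate))
  rt_col <- if (condition == "wt") "rt_wt" else "rt_dep"
  body_scale <- if (condition == "wt") 1 else config$body_fold_dep
  rel <- truth$abundance / mean(truth$abundance)
  tail_len <- as.integer(4 * config$coverage_decay_bp)

  # accumulate expected coverage, then one Poisson draw per base
  mu <- lapply(lengths, function(n) list("+" = numeric(n), "-" = numeric(n)))
  for (i in seq_len(nrow(truth))) {
    chrom <- tus$chrom[i]
    strand <- truth$strand[i]
    len <- lengths[[chrom]]
    body <- config$coverage_depth * rel[i] * body_scale
    body_idx <- tus$start[i]:(tus$end[i] - 1L)
    mu[[chrom]][[strand]][body_idx + 1L] <-
      mu[[chrom]][[strand]][body_idx + 1L] + body
    d <- seq_len(tail_len)
    tail_pos <- downstream_pos(truth$true_tts[i], strand, d)
    ok <- tail_pos >= 0 & tail_pos < len
    tail_mu <- body * truth[[rt_col]][i] * exp(-d[ok] / config$coverage_decay_bp)
    idx <- tail_pos[ok] + 1L
    mu[[chrom]][[strand]][idx] <- mu[[chrom]][[strand]][idx] + tail_mu
  }
  # stable-RNA ballast equalizing expected totals across conditions
  decay_sum <- sum(exp(-seq_len(tail_len) / config$coverage_decay_bp))
  expected_total <- function(cond) {
    scale <- if (cond == "wt") 1 else config$body_fold_dep
    rt <- truth[[if (cond == "wt") "rt_wt" else "rt_dep"]]
    body <- config$coverage_depth * rel * scale
    sum(body * (tus$end - tus$start)) + sum(body * rt * decay_sum)
  }
  target <- 1.05 * max(expected_total("wt"), expected_total("dep"))
  ballast_end <- min(tus$start)
  if (ballast_end > 0) {
    ballast_mu <- (target - expected_total(condition)) / ballast_end
    first_chrom <- tus$chrom[which.min(tus$start)]
    idx <- seq_len(ballast_end)
    mu[[first_chrom]][["+"]][idx] <- mu[[first_chrom]][["+"]][idx] + ballast_mu
  }
  for (chrom in names(lengths)) {
    for (s in c("+", "-")) {
      track$values[[chrom]][[s]] <- as.numeric(rpois(lengths[[chrom]],
                                                     mu[[chrom]][[s]]))
    }
  }
  track
}

#' Simulate an RNA decay time course
#'
#' Percent RNA remaining follows `100 x 2^(-t / t_half)` with additive
#' Gaussian noise, clipped at zero (signal quantification cannot go
#' negative).
#'
#' @param t_half true half-life in minutes (> 0).
#' @param times sampling times in minutes.
#' @param noise_sd standard deviation of the additive noise, in percent
#'   units.
#' @param seed integer seed.
#' @return a tibble with `time` and `percent`.
#' @export
simulate_decay <- function(t_half, times = c(0, 5, 10, 15), noise_sd = 0,
                           seed = 1L) {
  if (t_half <= 0) abort("t_half must be > 0")
  set.seed(stream_seed(seed, "assay", 0, "decay"))
  percent <- 100 * 2^(-times / t_half)
  if (noise_sd > 0) percent <- percent + rnorm(length(times), sd = noise_sd)
  tibble(time = times, percent = pmax(percent, 0))
}

#' Write a complete synthetic dataset to disk
#'
#' Generates the genome, TU annotation, ground-truth table, Term-seq
#' 3'-end tracks for every condition/replicate, and one coverage track
#' per condition, and writes them as FASTA, GFF3, TSV and paired
#' plus/minus bedGraph files. Rerunning with the same config is
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, a named list of all file paths plus the in-memory
#'   objects.
#' @export
simulate_dataset <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("output directory %s exists and is not empty (use force = TRUE)",
                  out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    annotation = file.path(out_dir, "tus.gff3"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_tu_gff3(sim$tus, paths$annotation)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$termseq <- list()
  for (cond in c("wt", "dep")) {
    for (r in seq_len(config$replicates)) {
      tr <- simulate_termseq(sim$genome, sim$tus, sim$truth, cond, r, config)
      base <- file.path(out_dir, sprintf("termseq_%s_rep%d", cond, r))
      write_stranded_bedgraph(tr, paste0(base, ".plus.bedgraph"),
                              paste0(base, ".minus.bedgraph"))
      paths$termseq[[sprintf("%s_rep%d", cond, r)]] <- base
    }
    cov <- simulate_coverage(sim$genome, sim$tus, sim$truth, cond, config)
    base <- file.path(out_dir, sprintf("coverage_%s", cond))
    write_stranded_bedgraph(cov, paste0(base, ".plus.bedgraph"),
                            paste0(base, ".minus.bedgraph"))
    paths[[sprintf("coverage_%s", cond)]] <- base
  }
  invisible(c(paths, sim = list(sim)))
}
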