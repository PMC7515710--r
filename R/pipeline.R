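#' Build a pipeline run configuration
#'
#' Collects the file paths and every analysis threshold into one
#' validated list. The threshold defaults are the values the analysis is
#' defined with: a 200 nt TTS search window, a -1/+1 ratio cut of 1.1
#' and count difference cut of 5 per replicate, read-through declared at
#' index > 1 and strong read-through at > 2, 200 nt motif flanks, and
#' the span-classification parameters `alpha` = 0.2 and `min_overlap` =
#' 25 bp.
#'
#' @param genome path to the genome FASTA.
#' @param annotation path to the TU annotation.
#' @param annotation_format `"gff3"` or `"bed"`.
#' @param termseq named list (conditions `wt`, `dep`); each condition a
#'   list of replicates, each replicate a named character vector with
#'   elements `plus` and `minus` (bedGraph paths). At least two `wt`
#'   replicates are required.
#' @param coverage named list (conditions `wt`, `dep`) of named vectors
#'   with `plus`/`minus` coverage bedGraph paths.
#' @param out_dir output directory for result tables and the run report.
#' @param window,ratio_min,diff_min TTS-calling thresholds (see
#'   [call_primary_tts()]).
#' @param trt_cut,strong_cut TRT index cuts (strict `>`).
#' @param flank motif-scan flank length in nt.
#' @param alpha,min_overlap read-through span classification parameters
#'   (see [classify_trt()]).
#' @param read_length nominal read length for coverage-to-fragment
#'   conversion.
#' @param pfm_upstream,pfm_downstream terminator PFM window.
#' @param seed integer recorded in the run report (the analysis itself
#'   is deterministic).
#' @return a list of class `run_config`.
#' @export
run_config <- function(genome, annotation, termseq, coverage, out_dir,
                       annotation_format = "gff3",
                       window = 200L, ratio_min = 1.1, diff_min = 5,
                       trt_cut = 1, strong_cut = 2, flank = 200L,
                       alpha = 0.2, min_overlap = 25L, read_length = 150L,
                       pfm_upstream = 30L, pfm_downstream = 10L,
                       seed = 1L) {
  cfg <- list(
    genome = genome, annotation = annotation,
    annotation_format = annotation_format,
    termseq = termseq, coverage = coverage, out_dir = out_dir,
    window = as.integer(window), ratio_min = ratio_min, diff_min = diff_min,
    trt_cut = trt_cut, strong_cut = strong_cut, flank = as.integer(flank),
    alpha = alpha, min_overlap = as.integer(min_overlap),
    read_length = as.integer(read_length),
    pfm_upstream = as.integer(pfm_upstream),
    pfm_downstream = as.integer(pfm_downstream),
    seed = as.integer(seed)
  )
  for (key in c("genome", "annotation")) {
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1) {
      abort(sprintf("run_config: '%s' must be a single path", key))
    }
  }
  if (!all(c("wt", "dep") %in% names(cfg$termseq))) {
    abort("run_config: termseq must name conditions 'wt' and 'dep'")
  }
  if (length(cfg$termseq$wt) < 2) {
    abort("run_config: TTS calling needs >= 2 'wt' Term-seq replicates")
  }
  if (!all(c("wt", "dep") %in% names(cfg$coverage))) {
    abort("run_config: coverage must name conditions 'wt' and 'dep'")
  }
  thresholds <- c(cfg$window, cfg$ratio_min, cfg$diff_min, cfg$trt_cut,
                  cfg$strong_cut, cfg$flank, cfg$alpha, cfg$min_overlap,
                  cfg$read_length)
  if (any(thresholds <= 0)) abort("run_config: all thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; replicate entries
#' under `termseq:` and condition entries under `coverage:` are maps
#' with `plus:` and `minus:` paths. Missing keys fall back to the
#' defaults of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file.
#' @param out_dir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  for (key in c("genome", "annotation", "termseq", "coverage")) {
    if (is.null(raw[[key]])) abort(sprintf("config key '%s' is required", key))
  }
  fix_pair <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  raw$termseq <- lapply(raw$termseq, function(cond) lapply(cond, fix_pair))
  raw$coverage <- lapply(raw$coverage, fix_pair)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  if (is.null(raw$out_dir)) abort("config key 'out_dir' is required")
  do.call(run_config, raw)
}

# Mean of several tracks of identical shape (used to pool replicate
# Term-seq tracks for the metaplot).
track_mean <- function(tracks) {
  out <- tracks[[1]]
  for (chrom in names(out$values)) {
    for (s in c("+", "-")) {
      acc <- out$values[[chrom]][[s]]
      for (k in seq_along(tracks)[-1]) {
        acc <- acc + tracks[[k]]$values[[chrom]][[s]]
      }
      out$values[[chrom]][[s]] <- acc / length(tracks)
    }
  }
  out$label <- "mean"
  out
}

#' Run the full termination analysis
#'
#' Executes every stage on files declared in the configuration: load
#' genome and annotation; call primary TTSs on the wild-type Term-seq
#' replicates; compute per-condition metaplots around the called sites
#' and their -2/+2 decreases; extract the terminator PFM; scan U-tract
#' enrichment around stop codons; derive IGRs (called TTSs, with the
#' annotated TU 3' end as fallback for uncalled TUs); quantify TU and
#' IGR FPKMs per condition from the coverage tracks; compute, flag and
#' classify the TRT index per TU; and summarize. All result tables are
#' written as TSV/BED under `out_dir` together with a JSON run report
#' (thresholds, seed, per-stage counts). The analysis is deterministic:
#' identical inputs produce byte-identical outputs.
#'
#' @param config a `run_config` (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return invisibly, a list with all in-memory results (`tts_calls`,
#'   `metaplots`, `decreases`, `pfm`, `u_tracts`, `igrs`,
#'   `expressions`, `trt_records`, `trt_summary`, `ranks`, `report`).
#' @export
run_termseq_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  genome <- stage("load-genome", read_genome_fasta(config$genome))
  tus <- stage("load-annotation",
               read_tu_annotation(config$annotation, config$annotation_format))

  load_pair <- function(pair, kind, label) {
    read_stranded_bedgraph(pair[["plus"]], pair[["minus"]], genome,
                           kind = kind, label = label)
  }
  termseq <- stage("load-termseq", lapply(names(config$termseq), function(cond) {
    lapply(seq_along(config$termseq[[cond]]), function(r) {
      load_pair(config$termseq[[cond]][[r]], "three_prime_end",
                sprintf("%s_rep%d", cond, r))
    })
  }))
  names(termseq) <- names(config$termseq)
  coverage <- stage("load-coverage", lapply(names(config$coverage), function(cond) {
    load_pair(config$coverage[[cond]], "coverage", cond)
  }))
  names(coverage) <- names(config$coverage)

  tts_calls <- stage("call-tts", call_primary_tts(
    termseq$wt, tus, window = config$window,
    ratio_min = config$ratio_min, diff_min = config$diff_min
  ))
  write_tts_calls(tts_calls,
                  bed_path = file.path(config$out_dir, "tts_calls.bed"),
                  tsv_path = file.path(config$out_dir, "tts_calls.tsv"))

  metaplots <- stage("metaplot", lapply(termseq, function(reps) {
    metaplot(track_mean(reps), tts_calls)
  }))
  decreases <- vapply(metaplots, tts_decrease, numeric(1))
  for (cond in names(metaplots)) {
    utils::write.table(metaplots[[cond]],
                       file.path(config$out_dir, sprintf("metaplot_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pfm <- stage("terminator-pfm", extract_terminator_pfm(
    tts_calls, genome,
    upstream = config$pfm_upstream, downstream = config$pfm_downstream
  ))
  write_pfm_tsv(pfm, file.path(config$out_dir, "terminator_pfm.tsv"))

  u_tracts <- stage("motif-scan",
                    u_tract_enrichment(tus, genome, flank = config$flank))
  utils::write.table(u_tracts, file.path(config$out_dir, "u_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # called TTS where available, annotated TU 3' end otherwise
  tus_tts <- mutate(tus, tts = ifelse(
    tus$tu_id %in% tts_calls$tu_id,
    tts_calls$tts_pos[match(tus$tu_id, tts_calls$tu_id)],
    ifelse(tus$strand == "+", tus$end - 1L, tus$start)
  ))
  igrs <- stage("derive-igrs", derive_igrs(tus_tts))
  write_igr_bed(igrs, file.path(config$out_dir, "igrs.bed"))

  expressions <- stage("quantify", bind_rows(lapply(names(coverage), function(cond) {
    bind_rows(
      quantify_features(tus_tts, coverage[[cond]], config$read_length,
                        feature_kind = "TU", condition = cond),
      quantify_features(igrs, coverage[[cond]], config$read_length,
                        feature_kind = "IGR", condition = cond,
                        id_col = "igr_id")
    )
  })))

  fpkm_of <- function(kind, ids, cond) {
    sel <- expressions[expressions$feature_kind == kind &
                         expressions$condition == cond, ]
    sel$fpkm[match(ids, sel$feature_id)]
  }
  trt_input <- tibble(
    tu_id = igrs$upstream_tu_id, igr_id = igrs$igr_id,
    fpkm_tu_wt = fpkm_of("TU", igrs$upstream_tu_id, "wt"),
    fpkm_tu_dep = fpkm_of("TU", igrs$upstream_tu_id, "dep"),
    fpkm_igr_wt = fpkm_of("IGR", igrs$igr_id, "wt"),
    fpkm_igr_dep = fpkm_of("IGR", igrs$igr_id, "dep")
  )
  trt_records <- stage("trt-index", compute_trt_index(trt_input))
  trt_records <- stage("trt-classify", classify_trt(
    trt_records, tus_tts, igrs, coverage$dep,
    alpha = config$alpha, min_overlap = config$min_overlap
  ))
  utils::write.table(trt_records, file.path(config$out_dir, "trt_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  trt_summary <- stage("trt-summary", summarize_trt(trt_records, expressions))
  utils::write.table(trt_summary, file.path(config$out_dir, "trt_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  wt_tu <- filter(expressions, .data$feature_kind == "TU", .data$condition == "wt")
  ranks <- tibble(feature_id = wt_tu$feature_id, fpkm = wt_tu$fpkm,
                  rank = expression_rank_bins(wt_tu$fpkm))
  utils::write.table(ranks, file.path(config$out_dir, "expression_ranks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    seed = config$seed,
    thresholds = config[c("window", "ratio_min", "diff_min", "trt_cut",
                          "strong_cut", "flank", "alpha", "min_overlap",
                          "read_length")],
    counts = list(
      n_tus = nrow(tus), n_tts_calls = nrow(tts_calls),
      n_igrs = nrow(igrs), n_igr_pairs_skipped = attr(igrs, "n_skipped"),
      n_trt_records = nrow(trt_records),
      n_pfm_sequences = pfm$n_sequences
    ),
    decreases = as.list(decreases)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    tts_calls = tts_calls, metaplots = metaplots, decreases = decreases,
    pfm = pfm, u_tracts = u_tracts, igrs = igrs, expressions = expressions,
    trt_records = trt_records, trt_summary = trt_summary, ranks = ranks,
    report = report, tus = tus_tts
  ))
}
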