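#' Run the analysis pipeline from a single configuration
#'
#' Drives any subset of the stages \code{simulate}, \code{screen},
#' \code{trace}, \code{noise} and \code{spt} from one structured
#' configuration (a nested list, or a YAML file path). Each stage writes
#' its tables into \code{out_dir} together with a per-stage log, and a
#' machine-readable \code{manifest.json} records the package version, the
#' seed, the full configuration and every artifact produced, so that the
#' manifest alone suffices to reproduce a run. Reruns with the same
#' configuration are bit-identical for all deterministic stages.
#'
#' Configuration layout (all sections optional unless a stage needs
#' them):
#' \preformatted{
#' seed: 1
#' stages: [simulate, screen, trace, noise, spt]
#' simulate:
#'   trajectories: {n_tracks, motion_class, n_frames, dt, D_micro, ...}
#'   traces:       {n_cells, n_timepoints, dt_min, offset_mean_min, ...}
#'   transcriptome: {n_decoys, length_range, planted: [{transcript_id,
#'                  motif, n_copies, spacing}, ...]}
#' screen: {fasta, k, max_mismatch, min_repeats}
#' trace:  {traces, threshold, same_time_window}
#' noise:  {traces, shuffle_seed, n_shuffles}
#' spt:    {tracks, dt, min_frames, fit_lags_max}
#' }
#' Stage inputs (\code{fasta}, \code{traces}, \code{tracks}) default to
#' the files the \code{simulate} stage of the same run produced.
#'
#' @param config nested list or YAML file path.
#' @param out_dir artifact directory (created if missing).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% character(0)
  manifest <- list(package = "embryotrace",
                   version = as.character(utils::packageVersion("embryotrace")),
                   seed = seed, config = config, stages = list())
  log_stage <- function(stage, lines) {
    writeLines(lines, file.path(out_dir, paste0(stage, ".log")))
  }
  artifact <- function(...) file.path(out_dir, ...)

  for (stage in stages) {
    out <- switch(stage,
      simulate = {
        sc <- config$simulate %||% list()
        files <- character(0)
        if (!is.null(sc$trajectories)) {
          a <- sc$trajectories
          cohort <- gen_trajectory_cohort(
            n_tracks = a$n_tracks %||% 50L,
            motion_class = a$motion_class %||% "diffusive",
            n_frames = a$n_frames %||% 100L, dt = a$dt %||% 0.01,
            D_micro = a$D_micro %||% 0.28, v = a$v %||% 0,
            L_box = a$L_box, sigma_loc = a$sigma_loc %||% 0,
            seed = seed)
          write_tracks(cohort$tracks, artifact("tracks.csv"))
          write.csv(cohort$ground_truth,
                    artifact("tracks_ground_truth.csv"), row.names = FALSE)
          files <- c(files, "tracks.csv", "tracks_ground_truth.csv")
        }
        if (!is.null(sc$traces)) {
          a <- sc$traces
          a$seed <- a$seed %||% seed
          sim <- do.call(gen_trace_pairs, a)
          write_traces(sim$traces, artifact("traces.csv"))
          write.csv(sim$ground_truth, artifact("traces_ground_truth.csv"),
                    row.names = FALSE)
          files <- c(files, "traces.csv", "traces_ground_truth.csv")
        }
        if (!is.null(sc$transcriptome)) {
          a <- sc$transcriptome
          specs <- lapply(a$planted %||% list(), function(p)
            do.call(planted_repeat_spec, p))
          tt <- gen_transcriptome(specs, n_decoys = a$n_decoys %||% 0L,
                                  length_range =
                                    unlist(a$length_range %||% c(500, 2000)),
                                  seed = seed)
          write_fasta(tt$sequences, artifact("transcriptome.fasta"))
          write.table(tt$gene_map, artifact("gene_map.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          write.csv(tt$ground_truth,
                    artifact("transcriptome_ground_truth.csv"),
                    row.names = FALSE)
          files <- c(files, "transcriptome.fasta", "gene_map.tsv",
                     "transcriptome_ground_truth.csv")
        }
        files
      },
      screen = {
        sc <- config$screen %||% list()
        fasta <- sc$fasta %||% artifact("transcriptome.fasta")
        if (!file.exists(fasta))
          stop("screen stage: input FASTA not found: ", fasta,
               call. = FALSE)
        gm_path <- sc$gene_map %||% artifact("gene_map.tsv")
        gm <- if (file.exists(gm_path))
          read.delim(gm_path, stringsAsFactors = FALSE) else NULL
        res <- screen_transcriptome(read_fasta(fasta), gene_map = gm,
                                    k = sc$k %||% 20L,
                                    max_mismatch = sc$max_mismatch %||% 1L)
        res <- cross_gene_uniqueness_filter(res)
        res <- select_candidates(res, min_repeats = sc$min_repeats %||% 8L)
        write_clusters_tsv(res, artifact("clusters.tsv"))
        jsonlite::write_json(res$summary, artifact("screen_summary.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        c("clusters.tsv", "screen_summary.json")
      },
      trace = {
        sc <- config$trace %||% list()
        traces <- read_traces(sc$traces %||% artifact("traces.csv"))
        rec <- activation_records(
          traces, threshold = sc$threshold %||% "auto",
          same_time_window = sc$same_time_window %||% 5)
        write.csv(rec, artifact("activation_records.csv"),
                  row.names = FALSE)
        ms <- memory_statistics(rec)
        jsonlite::write_json(
          list(per_group = ms$per_group,
               p_value = if (!is.null(ms$test)) ms$test$p.value else NULL),
          artifact("memory_summary.json"), auto_unbox = TRUE, pretty = TRUE,
          dataframe = "rows", digits = NA)
        c("activation_records.csv", "memory_summary.json")
      },
      noise = {
        sc <- config$noise %||% list()
        traces <- read_traces(sc$traces %||% artifact("traces.csv"))
        outs <- allele_outputs(traces)
        rep_real <- allele_correlation(outs)
        rep_shuf <- random_pair_control(outs,
                                        n_shuffles = sc$n_shuffles %||% 1L,
                                        seed = sc$shuffle_seed %||% seed)
        ptc <- suppressWarnings(per_timepoint_correlation(traces))
        write.csv(outs, artifact("allele_outputs.csv"), row.names = FALSE)
        write.csv(ptc$series, artifact("per_timepoint_r.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
          list(paired = unclass(rep_real)[c("r", "rho", "k", "n", "p")],
               shuffled = unclass(rep_shuf)[c("r", "rho", "k", "n", "p")]),
          artifact("correlation_report.json"), auto_unbox = TRUE,
          pretty = TRUE, digits = NA)
        c("allele_outputs.csv", "per_timepoint_r.csv",
          "correlation_report.json")
      },
      spt = {
        sc <- config$spt %||% list()
        tracks <- read_tracks(sc$tracks %||% artifact("tracks.csv"))
        tracks <- filter_tracks(tracks, min_frames = sc$min_frames %||% 20L)
        cls <- classify_tracks(tracks, dt = sc$dt,
                               fit_lags = seq_len(sc$fit_lags_max %||% 10L))
        write.csv(cls, artifact("motion_classes.csv"), row.names = FALSE)
        "motion_classes.csv"
      },
      denoise = {
        sc <- config$denoise %||% list()
        if (is.null(sc$input))
          stop("denoise stage: 'input' TIFF required", call. = FALSE)
        frames <- read_movie_tiff(sc$input)
        den <- lapply(frames, denoise_image,
                      lambda = sc$lambda %||% 0.01, mu = sc$mu %||% 0.1,
                      psf_sigma = sc$psf_sigma %||% 1.3,
                      max_iter = sc$max_iter %||% 200L)
        write_movie_tiff(lapply(den, function(m) matrix(as.numeric(m),
                                                        nrow(m), ncol(m))),
                         artifact("denoised.tif"))
        "denoised.tif"
      },
      stop("unknown stage: ", stage, call. = FALSE))
    log_stage(stage, c(paste("stage:", stage),
                       paste("artifacts:", paste(out, collapse = ", "))))
    manifest$stages[[stage]] <- list(artifacts = out)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# strict top-level schema: unknown keys are configuration mistakes
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  known <- c("seed", "stages", "simulate", "screen", "trace", "noise",
             "spt", "denoise")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  known_stages <- c("simulate", "screen", "trace", "noise", "spt",
                    "denoise")
  bad <- setdiff(config$stages %||% character(0), known_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
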