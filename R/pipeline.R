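#' Pipeline configuration
#'
#' Resolves and validates the configuration of a full pipeline run.
#' Settings may come from a YAML config file, overridden by arguments
#' (the CLI maps its flags onto these arguments). The resolved
#' configuration is written next to the outputs of every run.
#'
#' @param mode `"timeseries"` (inputs are per-subject region time-series
#'   tables), `"matrices"` (inputs are per-subject signed correlation
#'   matrices; the connectivity stage is skipped) or `"simulate"`
#'   (a synthetic study is generated at the default group specs).
#' @param input_dir directory holding `subjects.tsv` (columns
#'   `subject_id`, `group`, `file`) and the per-subject files; unused in
#'   simulate mode.
#' @param parcellation_path parcellation table path; in simulate mode a
#'   fixture is generated when omitted.
#' @param tr_seconds repetition time (s) for time-series inputs.
#' @param scale wavelet analysis scale.
#' @param backbone_threshold consensus threshold (strict, in (0, 1)).
#' @param alpha gate level for the hierarchical tests, in (0, 1).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stochastic step.
#' @param log_level `"info"` or `"quiet"`.
#' @param config_file optional YAML file of the same keys; file values
#'   are overridden by non-missing arguments.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("timeseries", "matrices", "simulate"),
                            input_dir = NULL, parcellation_path = NULL,
                            tr_seconds = 2.43, scale = 2,
                            backbone_threshold = 0.9, alpha = 0.05,
                            out_dir = "semimetric_out", seed = 1,
                            log_level = c("info", "quiet"),
                            config_file = NULL) {
  given <- names(match.call())[-1]
  cfg <- list(mode = match.arg(mode), input_dir = input_dir,
              parcellation_path = parcellation_path,
              tr_seconds = tr_seconds, scale = scale,
              backbone_threshold = backbone_threshold, alpha = alpha,
              out_dir = out_dir, seed = as.integer(seed),
              log_level = match.arg(log_level))
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown config key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    for (k in names(file_cfg))
      if (!(k %in% given)) cfg[[k]] <- file_cfg[[k]]
    cfg$mode <- match.arg(cfg$mode, c("timeseries", "matrices", "simulate"))
    cfg$seed <- as.integer(cfg$seed)
  }
  if (cfg$backbone_threshold <= 0 || cfg$backbone_threshold >= 1)
    stop("backbone_threshold must lie in (0, 1)", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$mode != "simulate" && is.null(cfg$input_dir))
    stop(sprintf("mode '%s' requires input_dir", cfg$mode), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(cfg, log_con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  writeLines(line, log_con)
  if (cfg$log_level == "info") message(line)
  invisible(NULL)
}

#' Write a synthetic study as an input directory tree
#'
#' Emits what a pipeline run consumes: `parcellation.tsv`,
#' `subjects.tsv`, per-subject files (time-series tables or signed
#' correlation matrices, by `mode`), plus the generator's ground truth as
#' JSON.
#'
#' @param out_dir target directory.
#' @param control,case [group_spec()]s (defaults [control_spec()],
#'   [case_spec()]).
#' @param parc optional [parcellation()].
#' @param seed integer seed.
#' @param mode `"timeseries"` or `"matrix"` subject files.
#' @return the `make_group_study()` result, invisibly.
#' @export
simulate_study_files <- function(out_dir, control = control_spec(),
                                 case = case_spec(), parc = NULL,
                                 seed = 1,
                                 mode = c("matrix", "timeseries")) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_group_study(control = control, case = case, parc = parc,
                          seed = seed, mode = mode)
  study <- gen$study
  write_parcellation(study$parcellation,
                     file.path(out_dir, "parcellation.tsv"))
  manifest <- do.call(rbind, lapply(study$subjects, function(s) {
    fname <- sprintf("%s.%s.tsv", s$subject_id,
                     if (mode == "timeseries") "timeseries" else "corr")
    data.frame(subject_id = s$subject_id, group = s$group, file = fname,
               stringsAsFactors = FALSE)
  }))
  write.table(manifest, file.path(out_dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in study$subjects) {
    fname <- manifest$file[manifest$subject_id == s$subject_id]
    if (mode == "timeseries") {
      write_timeseries_table(gen$ground_truth$timeseries[[s$subject_id]],
                             file.path(out_dir, fname))
    } else {
      m <- s$correlation
      dimnames(m) <- list(study$parcellation$id, study$parcellation$id)
      write_matrix(m, file.path(out_dir, fname))
    }
  }
  truth <- lapply(gen$ground_truth$subjects, function(x)
    list(group = x$group,
         planted = apply(x$planted, 1, function(p)
           study$parcellation$id[p], simplify = FALSE)))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(gen)
}

#' Run the full semi-metric analysis pipeline
#'
#' Executes every stage on a directory of subject inputs: connectivity
#' (time-series mode only), non-negative truncation, distance
#' isomorphism, metric closure and edge classification per subject, then
#' the group analyses — gated hierarchical SMP tests, asymmetry test,
#' per-group consensus backbones, node-averaged difference map,
#' distance-ranked SMP profile and the correlation-distribution summary.
#' All artifacts are written under `config$out_dir`; every tabular file
#' carries the resolved-config hash in its `#` header and the resolved
#' configuration itself is saved as `config.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the `group_study`, the result tables
#'   and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  # fingerprint the analysis-relevant settings only: where the outputs go
  # (and how chatty the run is) must not change the recorded provenance
  chash <- config_hash(unclass(config)[setdiff(names(config),
                                               c("out_dir", "log_level"))])
  hdr <- c(sprintf("config: %s", chash),
           sprintf("package: semimetric %s",
                   as.character(utils::packageVersion("semimetric"))),
           sprintf("seed: %d", config$seed))
  set.seed(config$seed)
  pipeline_log(config, log_con, "run start (mode=%s, seed=%d, config=%s)",
               config$mode, config$seed, chash)

  # ---- assemble subjects ---------------------------------------------------
  if (config$mode == "simulate") {
    sim_dir <- file.path(config$out_dir, "simulated_input")
    simulate_study_files(sim_dir, seed = config$seed, mode = "matrix")
    input_dir <- sim_dir
    mode <- "matrices"
    pipeline_log(config, log_con, "simulated study written to %s", sim_dir)
  } else {
    input_dir <- config$input_dir
    mode <- config$mode
  }
  parc_path <- if (!is.null(config$parcellation_path))
    config$parcellation_path else file.path(input_dir, "parcellation.tsv")
  parc <- read_parcellation(parc_path)
  manifest <- read.table(file.path(input_dir, "subjects.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  subj_dir <- file.path(config$out_dir, "subjects")
  dir.create(subj_dir, showWarnings = FALSE)

  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    stage <- "read"
    res <- tryCatch({
      path <- file.path(input_dir, manifest$file[i])
      if (mode == "timeseries") {
        ts <- read_timeseries_table(path, tr_seconds = config$tr_seconds,
                                    parc = parc)
        stage <- "connectivity"
        conn <- timeseries_to_proximity(ts, scale = config$scale)
      } else {
        m <- read_matrix(path, as = "matrix")
        m <- m[parc$id, parc$id]
        stage <- "connectivity"
        np <- nonnegative_proximity(m)
        conn <- list(graph = np$graph, correlation = m,
                     n_negative = np$n_negative)
      }
      stage <- "closure"
      cl <- metric_closure(proximity_to_distance(conn$graph))
      stage <- "write"
      write_matrix(conn$graph,
                   file.path(subj_dir, paste0(sid, ".proximity.tsv")),
                   comments = hdr)
      write_matrix(distance_graph(cl$closed_distances, parc$id),
                   file.path(subj_dir, paste0(sid, ".closed.tsv")),
                   comments = hdr)
      write_edge_classification(
        cl, file.path(subj_dir, paste0(sid, ".edges.tsv")), comments = hdr)
      list(subject_id = sid, group = manifest$group[i],
           proximity = conn$graph, closure = cl,
           correlation = conn$correlation, n_negative = conn$n_negative)
    }, error = function(e) {
      stop(sprintf("stage '%s' failed for subject %s: %s",
                   stage, sid, conditionMessage(e)), call. = FALSE)
    })
    subjects[[sid]] <- res
    pipeline_log(config, log_con, "subject %s: SMP = %.4f", sid,
                 smp(res$closure))
  }

  groups <- unique(manifest$group)
  study <- group_study(subjects, parc, groups = groups)

  # ---- group analyses ------------------------------------------------------
  profiles <- study_smp_profiles(study)
  smp_table <- gated_hierarchy_test(study, alpha = config$alpha,
                                    profiles = profiles)
  write_table_with_comments(smp_table,
                            file.path(config$out_dir, "smp_table.tsv"), hdr)
  jsonlite::write_json(smp_table,
                       file.path(config$out_dir, "smp_table.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  asym <- asymmetry_test(study, profiles = profiles)
  backbones <- list()
  for (g in study$groups) {
    bb <- backbone(study, group = g,
                   threshold = config$backbone_threshold)
    backbones[[g]] <- bb
    write_table_with_comments(
      bb, file.path(config$out_dir, sprintf("backbone_%s.tsv", g)), hdr)
  }
  scores <- group_difference_map(study)
  write_table_with_comments(
    data.frame(node_id = names(scores), score = as.numeric(scores),
               stringsAsFactors = FALSE),
    file.path(config$out_dir, "node_scores.tsv"), hdr)
  ranked <- distance_ranked_smp(study, profiles = profiles)
  write_table_with_comments(
    ranked, file.path(config$out_dir, "distance_ranked_smp.tsv"), hdr)
  corr_summary <- tryCatch(
    correlation_distribution_summary(study),
    error = function(e) NULL)
  report <- list(config_hash = chash,
                 groups = study$groups,
                 asymmetry = list(U = asym$U, p_value = asym$p_value),
                 correlation_summary = corr_summary$per_group,
                 negative_count_test = corr_summary$negative_count_test)
  jsonlite::write_json(report,
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg_out <- unclass(config)
  cfg_out$config_hash <- chash
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  pipeline_log(config, log_con, "run complete: %d subjects, %d region sets",
               length(subjects), nrow(smp_table))
  invisible(list(study = study, profiles = profiles,
                 smp_table = smp_table, asymmetry = asym,
                 backbones = backbones, node_scores = scores,
                 distance_ranked = ranked,
                 correlation_summary = corr_summary,
                 out_dir = config$out_dir, config_hash = chash))
}
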