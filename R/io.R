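#' Read and write per-sample assay tables
#'
#' The sample table is a long CSV with mandatory header `sample_id, group,
#' stage, conc_ng_ml, gene, region, replicate, meth_ratio,
#' recovery_signal`: one row per sample x locus x replicate (24 rows per
#' sample for the 6-locus duplicate panel). Reading validates the file and
#' fails with row numbers on missing columns, duplicate
#' (sample, locus, replicate) keys, or ratios outside \[0,1\]; an empty
#' `meth_ratio` field encodes a non-evaluable (no recovery) measurement.
#'
#' @param path CSV path.
#' @param panel the [LocusPanel-class] defining locus order.
#' @return `readSampleTable()` returns a [HiSAExperiment-class];
#'   `writeSampleTable()` returns `path` invisibly.
#' @export
readSampleTable <- function(path, panel = defaultLocusPanel()) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "stage", "conc_ng_ml", "gene", "region",
            "replicate", "meth_ratio", "recovery_signal")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  tab$locus <- paste0(tab$gene, "_R", tab$region)
  key <- paste(tab$sample_id, tab$locus, tab$replicate)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (sample, locus, replicate) at row ", dup + 1L,
         ": ", key[dup])
  }
  bad <- which(!is.na(tab$meth_ratio) &
                 (tab$meth_ratio < 0 | tab$meth_ratio > 1))
  if (length(bad))
    stop("meth_ratio outside [0,1] at row(s): ",
         paste(head(bad + 1L, 5), collapse = ", "))
  badr <- which(!is.na(tab$recovery_signal) & tab$recovery_signal < 0)
  if (length(badr))
    stop("negative recovery_signal at row(s): ",
         paste(head(badr + 1L, 5), collapse = ", "))
  unknown <- setdiff(unique(tab$locus), locusNames(panel))
  if (length(unknown))
    stop("unknown locus/loci: ", paste(unknown, collapse = ", "))
  samples <- unique(tab$sample_id)
  loci <- locusNames(panel)
  mk <- function() matrix(NA_real_, length(loci), length(samples),
                          dimnames = list(loci, samples))
  meth1 <- mk(); meth2 <- mk(); rec1 <- mk(); rec2 <- mk()
  i <- cbind(match(tab$locus, loci), match(tab$sample_id, samples))
  r1 <- tab$replicate == 1
  meth1[i[r1, , drop = FALSE]] <- tab$meth_ratio[r1]
  meth2[i[!r1, , drop = FALSE]] <- tab$meth_ratio[!r1]
  rec1[i[r1, , drop = FALSE]] <- tab$recovery_signal[r1]
  rec2[i[!r1, , drop = FALSE]] <- tab$recovery_signal[!r1]
  first <- tab[match(samples, tab$sample_id), ]
  cd <- DataFrame(group = first$group, stage = as.character(first$stage),
                  conc_ng_ml = first$conc_ng_ml, row.names = samples)
  HiSAExperiment(meth1, meth2, rec1, rec2, cd, panel = panel)
}

#' @param se a [HiSAExperiment-class].
#' @rdname readSampleTable
#' @export
writeSampleTable <- function(se, path) {
  loci <- rownames(se)
  gene <- sub("_R[12]$", "", loci)
  region <- as.integer(sub("^.*_R", "", loci))
  cd <- colData(se)
  rows <- lapply(seq_len(ncol(se)), function(j) {
    data.frame(sample_id = colnames(se)[j], group = cd$group[j],
               stage = cd$stage[j], conc_ng_ml = cd$conc_ng_ml[j],
               gene = rep(gene, 2), region = rep(region, 2),
               replicate = rep(1:2, each = length(loci)),
               meth_ratio = c(assay(se, "meth1")[, j],
                              assay(se, "meth2")[, j]),
               recovery_signal = c(assay(se, "rec1")[, j],
                                   assay(se, "rec2")[, j]))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write trajectory tables
#'
#' Draws CSV: `patient_id, day, fc, cea, burden, line`; events CSV:
#' `patient_id, day, type`.
#'
#' @param draws_path,events_path CSV paths.
#' @return `readTrajectoryTable()` returns a named list of
#'   [Trajectory-class] objects; `writeTrajectoryTable()` returns the paths
#'   invisibly.
#' @export
readTrajectoryTable <- function(draws_path, events_path) {
  d <- read.csv(draws_path, stringsAsFactors = FALSE)
  e <- read.csv(events_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "fc", "cea", "burden", "line")
  if (length(setdiff(need, colnames(d))))
    stop("draws table is missing column(s): ",
         paste(setdiff(need, colnames(d)), collapse = ", "))
  if (length(setdiff(c("patient_id", "day", "type"), colnames(e))))
    stop("events table is missing column(s)")
  lapply(setNames(nm = unique(d$patient_id)), function(p) {
    dd <- d[d$patient_id == p, c("day", "fc", "cea", "burden", "line")]
    dd <- dd[order(dd$day), ]; rownames(dd) <- NULL
    ee <- e[e$patient_id == p, c("day", "type")]
    ee <- ee[order(ee$day), ]; rownames(ee) <- NULL
    new("Trajectory", patientId = p, draws = dd, events = ee)
  })
}

#' @param trajectories list of [Trajectory-class] objects.
#' @rdname readTrajectoryTable
#' @export
writeTrajectoryTable <- function(trajectories, draws_path, events_path) {
  if (methods::is(trajectories, "Trajectory"))
    trajectories <- list(trajectories)
  d <- do.call(rbind, lapply(trajectories, function(t)
    cbind(patient_id = t@patientId, draws(t))))
  e <- do.call(rbind, lapply(trajectories, function(t) {
    ev <- events(t)
    if (!nrow(ev)) return(NULL)
    cbind(patient_id = t@patientId, ev)
  }))
  if (is.null(e))
    e <- data.frame(patient_id = character(0), day = integer(0),
                    type = character(0))
  write.csv(d, draws_path, row.names = FALSE)
  write.csv(e, events_path, row.names = FALSE)
  invisible(c(draws = draws_path, events = events_path))
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: obtain a cohort (simulate under a [cohortSpec()] or
#' read a sample CSV), score it, evaluate the diagnostic performance of M,
#' R and Fc (full-fit ROC with DeLong CIs, logistic fit, stratified k-fold
#' cross-validated ROC and its DeLong comparison with the full Fc ROC),
#' optionally analyze monitoring trajectories, and write all artifacts
#' (scores CSV, evaluation JSON, monitoring JSON, log) stamped with the
#' seed and a config hash. Given a seed, outputs are deterministic.
#'
#' @param config configuration list or path to a YAML file with blocks
#'   `seed`, `output_dir`, optional `sample_csv`, optional `cohort`
#'   (arguments to [cohortSpec()]), `scoring` (arguments to
#'   [scoringConfig()]), `evaluation` (`kfold`), `monitoring` (`n_patients`
#'   or `draws_csv`/`events_csv`, plus rise-rule settings).
#' @return invisibly, a list with the scores data.frame, the evaluation
#'   list, the monitoring list and the output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfgHash <- .configHash(config)
  set.seed(seed)

  cfg <- do.call(scoringConfig, config$scoring %||% list())
  se <- if (!is.null(config$sample_csv)) {
    readSampleTable(config$sample_csv)
  } else {
    spec <- do.call(cohortSpec, config$cohort %||% list())
    simulateCcfdnaCohort(spec, seed = NULL)
  }
  scores <- tryCatch(scoreCohort(se, cfg),
                     error = function(e) stop("scoring stage: ",
                                              conditionMessage(e)))
  scores_path <- file.path(out_dir, "scores.csv")
  write.csv(scores, scores_path, row.names = FALSE)

  evaluation <- tryCatch({
    y <- scores$group == "CRC"
    kfold <- config$evaluation$kfold %||% 5L
    fit <- suppressWarnings(fitLogisticScores(scores$M, scores$R, y))
    rocs <- list(M = rocAuc(scores$M, y), R = rocAuc(scores$R, y),
                 Fc = rocAuc(scores$Fc, y))
    cv <- stratifiedKfoldCv(scores$M, scores$R, y, k = kfold, seed = NULL)
    cmp <- delongTest(scores$Fc, attr(cv, "oof"), y)
    list(
      n_cases = sum(y), n_controls = sum(!y),
      logistic = list(coefficients = as.list(fit$coefficients),
                      se = as.list(fit$se), converged = fit$converged),
      auc = lapply(rocs, function(r)
        list(auc = auc(r), ci = aucCI(r))),
      cv = list(kfold = kfold, auc = auc(cv), ci = aucCI(cv)),
      fc_vs_cv = list(delta = cmp$delta, p = cmp$p))
  }, error = function(e) stop("evaluation stage: ", conditionMessage(e)))

  monitoring <- NULL
  mon <- config$monitoring
  if (!is.null(mon)) {
    monitoring <- tryCatch({
      trajs <- if (!is.null(mon$draws_csv)) {
        readTrajectoryTable(mon$draws_csv, mon$events_csv)
      } else {
        npat <- mon$n_patients %||% 1L
        tspec <- do.call(trajectorySpec,
                         mon$trajectory %||% list())
        lapply(setNames(nm = paste0("P", seq_len(npat))), function(p)
          simulateTrajectory(tspec, patient_id = p, seed = NULL))
      }
      lapply(trajs, function(t) {
        lt <- leadTime(t, threshold = mon$threshold %||% 0.30,
                       confirm = mon$confirm %||% 2L)
        d <- draws(t)
        span <- mon$span_days %||% 60
        cFc <- smoothCurve(d$day, d$fc, span)
        cBur <- smoothCurve(d$day, d$burden, span)
        cCea <- smoothCurve(d$day, d$cea, span)
        lt$concordance <- list(
          fc_burden = trendConcordance(cFc, cBur),
          fc_cea = trendConcordance(cFc, cCea))
        lt
      })
    }, error = function(e) stop("monitoring stage: ", conditionMessage(e)))
  }

  eval_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(c(list(seed = seed, config_hash = cfgHash),
                         evaluation),
                       eval_path, auto_unbox = TRUE, digits = NA)
  paths <- list(scores = scores_path, evaluation = eval_path)
  if (!is.null(monitoring)) {
    mon_path <- file.path(out_dir, "monitoring.json")
    jsonlite::write_json(c(list(seed = seed, config_hash = cfgHash),
                           list(patients = monitoring)),
                         mon_path, auto_unbox = TRUE, digits = NA)
    paths$monitoring <- mon_path
  }
  log_path <- file.path(out_dir, "pipeline.log")
  writeLines(c(sprintf("seed: %s", seed),
               sprintf("config_hash: %s", cfgHash),
               sprintf("samples: %d", ncol(se)),
               sprintf("artifacts: %s",
                       paste(unlist(paths), collapse = ", "))),
             log_path)
  paths$log <- log_path
  invisible(list(scores = scores, evaluation = evaluation,
                 monitoring = monitoring, paths = paths))
}

.configHash <- function(config) {
  # hash the analysis-relevant configuration, not the output location
  config$output_dir <- NULL
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
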