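#' Pipeline configuration
#'
#' Describes one end-to-end analysis: where recordings come from (a
#' [cohort_spec()] to simulate, or a directory holding `subjects.tsv` plus
#' recording files), which biomarker registry to extract, which visit
#' trains and which evaluates, how biomarkers are selected, and the seeds.
#' Subjects lacking the training visit are never trained on and form the
#' held-out prediction set.
#'
#' @param input a [cohort_spec()] or a directory path.
#' @param registry biomarker registry (default [default_registry()]).
#' @param training_visit,evaluation_visit visit indices (defaults 2 and 1;
#'   must differ).
#' @param selection `"genetic"`, `"elastic_net"` or `"single:<biomarker>"`.
#' @param genetic a [genetic_search_config()].
#' @param elastic_net an [elastic_net_config()].
#' @param alpha,k_min difference-map correction parameters.
#' @param half_split_iterations half-split CV iterations; 0 disables the CV
#'   stage.
#' @param seed master seed for selection and cross-validation randomness.
#' @param psd_window_length Welch window length (s) for extraction.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, registry = default_registry(),
                            training_visit = 2L, evaluation_visit = 1L,
                            selection = "genetic",
                            genetic = genetic_search_config(),
                            elastic_net = elastic_net_config(),
                            alpha = 0.05, k_min = 3,
                            half_split_iterations = 1000, seed = 1L,
                            psd_window_length = 4) {
  if (training_visit == evaluation_visit)
    stop("training and evaluation visits must differ")
  if (is.character(input) && !dir.exists(input))
    stop("input directory does not exist: ", input)
  if (!(is.character(input) || inherits(input, "cohort_spec")))
    stop("input must be a cohort_spec or a directory path")
  ok <- selection %in% c("genetic", "elastic_net") ||
    startsWith(selection, "single:")
  if (!ok) stop("selection must be 'genetic', 'elastic_net' or 'single:<biomarker>'")
  structure(list(input = input, registry = registry,
                 training_visit = as.integer(training_visit),
                 evaluation_visit = as.integer(evaluation_visit),
                 selection = selection, genetic = genetic,
                 elastic_net = elastic_net, alpha = alpha, k_min = k_min,
                 half_split_iterations = half_split_iterations,
                 seed = as.integer(seed),
                 psd_window_length = psd_window_length),
            class = "pipeline_config")
}

# polynomial rolling hash of a deparsed object, for report provenance
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

# read a cohort written by write_cohort()
read_cohort <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_len(nrow(tab))) {
    recs[[paste0(tab$subject_id[i], "-v1")]] <-
      read_recording(file.path(dir, tab$visit1_file[i]))
    if (nzchar(tab$visit2_file[i]))
      recs[[paste0(tab$subject_id[i], "-v2")]] <-
        read_recording(file.path(dir, tab$visit2_file[i]))
  }
  tab$has_visit2 <- nzchar(tab$visit2_file)
  list(recordings = recs, subjects = tab)
}

#' Run the full diagnostic-index pipeline
#'
#' Executes the processing flow: simulate or load the cohort; extract the
#' biomarker battery from every recording; map group differences on the
#' training visit with the binomial channel correction; reduce to median
#' features over significant channels (channel sets frozen from the
#' training map); rank single biomarkers by MCC; select a biomarker set
#' (genetic search, elastic net, or a named single biomarker); fit the
#' logistic index on the training visit; predict the evaluation visit for
#' all subjects and for the held-out subjects that lack a training-visit
#' recording; and estimate the half-split cross-validation lower bound.
#' Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return An `evaluation_report` list: `selected_biomarkers`, `model`,
#'   `metrics` (train / evaluation_all / evaluation_heldout / half_split),
#'   `mc_thresholds` for the held-out sample size, `difference_map_summary`,
#'   `ranking`, `subjects`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- .stage("cohort", {
    if (inherits(config$input, "cohort_spec")) generate_cohort(config$input)
    else read_cohort(config$input)
  })
  tensors <- .stage("extract", lapply(
    cohort$recordings, extract_battery, registry = config$registry,
    psd_window_length = config$psd_window_length))
  visit_of <- vapply(tensors, function(t) t$visit, integer(1))
  train_tensors <- tensors[visit_of == config$training_visit]
  eval_tensors <- tensors[visit_of == config$evaluation_visit]
  if (!length(train_tensors)) stop("no recordings at the training visit")

  dmap <- .stage("difference_map",
                 difference_map(train_tensors, alpha = config$alpha,
                                k_min = config$k_min))
  feat_train <- .stage("features", reduce_to_features(train_tensors, dmap))
  feat_eval <- .stage("features", reduce_to_features(eval_tensors, dmap))
  bm_cols <- setdiff(names(feat_train), c("subject_id", "group", "visit"))
  complete <- stats::complete.cases(feat_train[, bm_cols, drop = FALSE])
  feat_train <- feat_train[complete, , drop = FALSE]
  y_train <- as.integer(feat_train$group == "AD-converter")
  X_train <- feat_train[, bm_cols, drop = FALSE]

  ranking <- .stage("ranking", rank_single_biomarkers(X_train, y_train))

  sel <- .stage("selection", {
    if (config$selection == "genetic") {
      gcfg <- config$genetic
      gcfg$seed <- derive_seed(config$seed, component = 71L)
      # small candidate pools (few biomarkers past the correction): seed
      # with the whole pool rather than failing
      gcfg$seed_set_size <- min(gcfg$seed_set_size, length(bm_cols))
      gs <- genetic_search(X_train, y_train, gcfg)
      list(biomarkers = gs$biomarkers, model = gs$model,
           trace = gs$criterion_trace)
    } else if (config$selection == "elastic_net") {
      ecfg <- config$elastic_net
      ecfg$seed <- derive_seed(config$seed, component = 72L)
      en <- fit_elastic_net(X_train, y_train, ecfg)
      list(biomarkers = en$biomarkers, model = en$model, trace = NULL)
    } else {
      bm <- sub("^single:", "", config$selection)
      if (!bm %in% bm_cols)
        stop("selection biomarker not in the feature table: ", bm)
      list(biomarkers = bm,
           model = fit_logistic(X_train[, bm, drop = FALSE], y_train),
           trace = NULL)
    }
  })

  evaluate_on <- function(feat) {
    keep <- stats::complete.cases(feat[, sel$biomarkers, drop = FALSE])
    feat <- feat[keep, , drop = FALSE]
    y <- as.integer(feat$group == "AD-converter")
    if (length(unique(y)) < 2) return(NULL)
    outcome_metrics(predict(sel$model,
                            feat[, sel$biomarkers, drop = FALSE])$class, y)
  }
  train_subjects <- unique(feat_train$subject_id)
  heldout <- feat_eval[!feat_eval$subject_id %in% train_subjects, ,
                       drop = FALSE]
  metrics <- .stage("evaluate", list(
    train = evaluate_on(feat_train),
    evaluation_all = evaluate_on(feat_eval),
    evaluation_heldout = evaluate_on(heldout)))

  metrics$half_split <- if (config$half_split_iterations > 0)
    .stage("crossval", half_split_cv(
      X_train[, sel$biomarkers, drop = FALSE], y_train,
      n_iterations = config$half_split_iterations,
      seed = derive_seed(config$seed, component = 73L)))
  else NULL

  mc <- if (nrow(heldout) > 0 && length(unique(heldout$group)) > 1)
    monte_carlo_thresholds(nrow(heldout),
                           sum(heldout$group == "AD-converter"),
                           seed = derive_seed(config$seed, component = 74L))
  else NULL

  structure(list(
    selected_biomarkers = sel$biomarkers,
    model = sel$model,
    criterion_trace = sel$trace,
    metrics = metrics,
    mc_thresholds = mc,
    difference_map_summary = list(
      n_biomarkers = length(dmap$corrected_significant),
      n_corrected_significant = sum(dmap$corrected_significant),
      significant_biomarkers =
        names(dmap$corrected_significant)[dmap$corrected_significant]),
    ranking = ranking,
    subjects = list(training = train_subjects,
                    heldout = unique(heldout$subject_id)),
    provenance = list(config_hash = .config_hash(config),
                      seed = config$seed,
                      selection = config$selection,
                      training_visit = config$training_visit,
                      evaluation_visit = config$evaluation_visit,
                      version = as.character(utils::packageVersion("eegdx")))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  selected biomarkers (%d): %s\n",
              length(x$selected_biomarkers),
              paste(x$selected_biomarkers, collapse = ", ")))
  for (nm in c("train", "evaluation_all", "evaluation_heldout")) {
    if (is.null(x$metrics[[nm]])) next
    cat(sprintf("  %-20s", nm)); print(x$metrics[[nm]])
  }
  if (!is.null(x$metrics$half_split)) {
    hs <- x$metrics$half_split
    cat(sprintf("  half-split medians   SE %.0f%%  SP %.0f%%  MCC %.2f  PLR %.1f\n",
                100 * hs["sensitivity"], 100 * hs["specificity"],
                hs["mcc"], hs["plr"]))
  }
  invisible(x)
}

# metrics list -> plain list for JSON
.metrics_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  if (inherits(m, "outcome_metrics")) unclass(m) else as.list(m)
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (machine-readable, reread by [read_report()]) and
#' `report.txt` (human-readable summary) into `dir`. Disabled sections are
#' recorded as absent, not as zeros.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return path of the JSON report, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    selected_biomarkers = report$selected_biomarkers,
    coefficients = c("(Intercept)" = report$model$beta0,
                     report$model$betas),
    metrics = lapply(report$metrics, .metrics_to_list),
    mc_thresholds = as.list(report$mc_thresholds),
    difference_map_summary = report$difference_map_summary,
    subjects = report$subjects,
    provenance = report$provenance)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  cat(sprintf("\nconfig hash %s, seed %d\n",
              report$provenance$config_hash, report$provenance$seed))
  invisible(path)
}

#' Read back a JSON evaluation report
#' @param path path to `report.json`.
#' @return the parsed report list.
#' @export
read_report <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)
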