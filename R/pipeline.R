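# File-to-file orchestration: digest -> quantify -> screen -> select ->
# report, with config validation and a run manifest.

.CONFIG_SCHEMA <- list(
  top_n_d = list(type = "integer", min = 1),
  binder_threshold = list(type = "numeric"),
  expect_threshold = list(type = "numeric", gt = 0),
  mz_min = list(type = "numeric", gt = 0),
  mz_max = list(type = "numeric", gt = 0),
  charges = list(type = "integer_vector", min = 1),
  min_length = list(type = "integer", min = 1),
  max_missed_cleavages = list(type = "integer", min = 0),
  require_both_replicates = list(type = "logical"),
  seed = list(type = "integer")
)

#' Default pipeline configuration
#'
#' @return Named list with the documented configuration keys and their
#'   defaults (top_n_d = 30, binder_threshold = 0, expect_threshold = 0.05,
#'   m/z window 350-1800, charges 2-3, min_length 6,
#'   max_missed_cleavages 2, require_both_replicates = TRUE, seed = 1).
#' @export
defaultPipelineConfig <- function() {
  list(top_n_d = 30L, binder_threshold = 0, expect_threshold = 0.05,
       mz_min = 350, mz_max = 1800, charges = c(2L, 3L), min_length = 6L,
       max_missed_cleavages = 2L, require_both_replicates = TRUE, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Checks every key of a configuration (a named list, or a path to a YAML
#' file) for type and range against the documented schema; unknown keys are
#' rejected. All problems are reported together.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration (with defaults filled in),
#'   invisibly on success; otherwise an error listing each offending key.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  errs <- character()
  unknown <- setdiff(names(config), names(.CONFIG_SCHEMA))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  full <- utils::modifyList(defaultPipelineConfig(), config)
  for (key in names(.CONFIG_SCHEMA)) {
    sch <- .CONFIG_SCHEMA[[key]]
    v <- full[[key]]
    bad <- switch(sch$type,
      integer = length(v) != 1L || !is.numeric(v) || v != round(v),
      numeric = length(v) != 1L || !is.numeric(v) || !is.finite(v),
      integer_vector = length(v) == 0L || !is.numeric(v) ||
        any(v != round(v)),
      logical = length(v) != 1L || !is.logical(v))
    if (bad) {
      errs <- c(errs, paste0(key, ": expected ", sch$type))
      next
    }
    if (!is.null(sch$min) && any(v < sch$min))
      errs <- c(errs, paste0(key, ": must be >= ", sch$min))
    if (!is.null(sch$gt) && any(v <= sch$gt))
      errs <- c(errs, paste0(key, ": must be > ", sch$gt))
  }
  if (!length(errs) && full$mz_min >= full$mz_max)
    errs <- c(errs, "mz_min: must be < mz_max")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(full)
}

.windowFromConfig <- function(config) {
  observabilityWindow(mzMin = config$mz_min, mzMax = config$mz_max,
                      charges = config$charges,
                      minLength = config$min_length,
                      maxMissedCleavages = config$max_missed_cleavages)
}

#' Run the full file-to-file pipeline
#'
#' Reads a proteome FASTA, one or more peptide-evidence TSVs and an
#' annotation table; assigns categories; filters evidence and computes
#' emPAI; screens and selects candidates; writes `abundance.tsv`,
#' `composition.tsv`, `candidates.tsv`, `summary.txt` and a `run_log.txt`
#' manifest (parameters, input checksums, package version) under `outDir`.
#' Inputs are never modified; outputs are confined to `outDir`.
#'
#' @param proteomeFasta Path to the protein FASTA.
#' @param evidencePaths Character vector of evidence TSV paths (one or
#'   more; replicate labels come from the files' `replicate` column).
#' @param annotationsPath Path to the annotation TSV.
#' @param config Named list or YAML path; see [validateConfig()].
#' @param outDir Output directory.
#' @param rules Category-rule data.frame; default
#'   [defaultCategoryRules()].
#' @param bindingModel A [BindingModel-class] or path to a model JSON;
#'   default [defaultBindingModel()].
#' @return Invisible list with the selection result and the paths written.
#' @export
runPipeline <- function(proteomeFasta, evidencePaths, annotationsPath,
                        config = defaultPipelineConfig(), outDir,
                        rules = defaultCategoryRules(),
                        bindingModel = NULL) {
  config <- validateConfig(config)
  set.seed(config$seed)
  proteins <- readProteomeFasta(proteomeFasta)
  ann <- readAnnotations(annotationsPath)
  proteins <- assignCategories(proteins, rules, overrides = ann)
  evidence <- do.call(rbind, lapply(evidencePaths, readEvidence))
  ev <- filterEvidence(evidence, config$expect_threshold)
  window <- .windowFromConfig(config)
  records <- computeEmpai(ev, proteins, window)
  if (is.character(bindingModel)) bindingModel <- readBindingModel(bindingModel)
  sel <- selectCandidates(records, proteins = proteins,
                          config = selectionConfig(
                            topNd = config$top_n_d,
                            binderThreshold = config$binder_threshold,
                            requireBothReplicates =
                              config$require_both_replicates,
                            expectThreshold = config$expect_threshold),
                          bindingModel = bindingModel)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ranked <- rankByEmpai(records)
  abPath <- file.path(outDir, "abundance.tsv")
  write.table(ranked, abPath, sep = "\t", quote = FALSE, row.names = FALSE)
  compPath <- file.path(outDir, "composition.tsv")
  write.table(compositionSummary(records), compPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  repPaths <- writeReport(sel, outDir, records = records)
  logPath <- file.path(outDir, "run_log.txt")
  inputs <- c(proteomeFasta, evidencePaths, annotationsPath)
  writeLines(c(
    paste0("nucleoprofiler ", as.character(packageVersion("nucleoprofiler"))),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "parameters:",
    paste0("  ", names(config), " = ",
           vapply(config, function(v) paste(v, collapse = ","),
                  character(1L))),
    "input checksums (md5):",
    paste0("  ", inputs, " ", unname(tools::md5sum(inputs)))
  ), logPath)
  invisible(list(selection = sel,
                 paths = c(abundance = abPath, composition = compPath,
                           candidates = repPaths[1L], summary = repPaths[2L],
                           run_log = logPath)))
}
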