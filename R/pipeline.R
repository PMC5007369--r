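# Run orchestration: configuration, stage sequencing, artifacts, report.

.STAGES <- c("simulate", "normalize", "quantify", "select", "mars", "verify_table")

.config_keys <- function() c(
  "stages", "out_dir", "seed",
  "volumes", "meta",                      # input paths (alternative to simulate)
  names(formals(synthetic_config)),       # generator parameters
  "preset", "fold_threshold", "alpha", "use_adjusted",
  "ror_threshold",
  "mars_max_bases", "mars_scheme", "mars_penalty",
  "fixture"                               # alternative fixture path
)

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' coerced to numeric or logical where possible; `stages` may be a
#' comma-separated list.  Unknown keys are rejected.
#'
#' @param path path to the configuration file.
#' @return a named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <-
      if (val %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(val) == "TRUE")
      else if (!is.na(num)) num
      else if (grepl(",", val)) trimws(strsplit(val, ",")[[1]])
      else val
  }
  cfg
}

.validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- list(stages = .STAGES, out_dir = NULL, seed = 1L,
                   preset = "discovery", ror_threshold = 1.5,
                   mars_max_bases = 21, mars_scheme = c("cv10", "split80_20"),
                   mars_penalty = 2)
  config <- utils::modifyList(defaults, config)
  if (identical(config$stages, "run")) config$stages <- .STAGES
  bad <- setdiff(config$stages, .STAGES)
  if (length(bad)) stop("unknown stage '", bad[1L], "'", call. = FALSE)
  config
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full quantification pipeline
#'
#' Executes the requested stages in their canonical order — simulate (or
#' ingest), normalize, quantify (fold ratios and RoR), select
#' (fold/p thresholds plus Venn classification), mars (classifier
#' validation), verify_table (fixture arithmetic check) — writing TSV and
#' JSON artifacts to `out_dir` when one is given, and returns a run
#' report.  The same configuration and seed reproduce the same report.
#'
#' @param config named list (or a path read by [read_run_config()]).
#'   Keys: `stages` (subset of the canonical stages, or `"run"`),
#'   `out_dir`, `seed`, either generator parameters (see
#'   [synthetic_config()]) or input paths `volumes`/`meta`, `preset` or
#'   explicit `fold_threshold`/`alpha`/`use_adjusted`, `ror_threshold`,
#'   `mars_max_bases`, `mars_scheme`, `mars_penalty`, `fixture`.
#' @return a list of class `run_report` with per-stage summaries.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  config <- .validate_run_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  thresholds <- if (!is.null(config$fold_threshold) || !is.null(config$alpha)) {
    utils::modifyList(differential_preset(config$preset),
                      config[intersect(names(config),
                                       c("fold_threshold", "alpha", "use_adjusted"))])
  } else differential_preset(config$preset)

  report <- list(package_version = as.character(utils::packageVersion("snoRoR")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = config$seed,
                 config_hash = .config_hash(config[setdiff(names(config), "out_dir")]),
                 stages = list())
  stages <- config$stages
  gs <- NULL
  truth <- NULL

  if ("simulate" %in% stages) {
    sim <- .stage("simulate", {
      keys <- intersect(names(config), names(formals(synthetic_config)))
      args <- config[keys]
      args$seed <- config$seed
      simulate_gelset(do.call(synthetic_config, args))
    })
    gs <- sim$gelset
    truth <- sim$truth
    if (!is.null(out_dir)) {
      write_gelset(gs, art("volumes.tsv"), art("gel_meta.tsv"))
      write_truth(truth, art("truth.tsv"))
    }
    report$stages$simulate <- list(n_spots = nrow(gs$volumes),
                                   n_gels = ncol(gs$volumes))
  } else if (!is.null(config$volumes)) {
    gs <- .stage("ingest", read_gelset(config$volumes, config$meta))
    report$stages$ingest <- list(n_spots = nrow(gs$volumes),
                                 n_gels = ncol(gs$volumes))
  }

  if ("normalize" %in% stages) {
    if (is.null(gs)) stop("stage 'normalize' failed: no gelset available", call. = FALSE)
    gs <- .stage("normalize", normalize_gelset(gs))
    bf <- attr(gs, "bias_factors")
    if (!is.null(out_dir)) {
      write_gelset(gs, art("normalized_volumes.tsv"), art("gel_meta.tsv"))
      utils::write.table(bf, art("bias_factors.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$stages$normalize <- list(reference_gel = gs$reference_gel,
                                    gain_range = range(bf$gain))
  }

  diff_ab <- diff_sno <- ror <- NULL
  if ("quantify" %in% stages) {
    if (is.null(gs)) stop("stage 'quantify' failed: no gelset available", call. = FALSE)
    ror <- .stage("quantify", ror_quantify(gs, threshold = config$ror_threshold))
    diff_ab <- .stage("quantify", do.call(differential_table,
                                          c(list(gs, channel = "Asc+"), thresholds)))
    diff_sno <- .stage("quantify", do.call(differential_table,
                                           c(list(gs, channel = "Asc-"), thresholds)))
    if (!is.null(out_dir)) {
      utils::write.table(ror, art("ror.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(diff_ab, art("differential_abundance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(diff_sno, art("differential_sno.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$stages$quantify <- list(
      n_spots_tested = sum(!is.na(diff_ab$p)),
      sno_calls = as.list(table(ror$sno_call)))
  }

  sel_ab <- sel_sno <- NULL
  if ("select" %in% stages) {
    if (is.null(diff_ab)) stop("stage 'select' failed: run 'quantify' first", call. = FALSE)
    sel_ab <- .stage("select", do.call(select_spots, c(list(diff_ab), thresholds)))
    sel_sno <- .stage("select", do.call(select_sno_spots,
                                        c(list(diff_sno, ror), thresholds)))
    venn <- venn_classify(sel_ab$spot_id, sel_sno$spot_id)
    report$stages$select <- list(
      abundance_selected = nrow(sel_ab),
      sno_selected = nrow(sel_sno),
      venn = venn[c("both", "abundance_only", "sno_only")])
  }

  if ("mars" %in% stages) {
    if (is.null(gs) || is.null(sel_ab)) {
      stop("stage 'mars' failed: run 'select' first", call. = FALSE)
    }
    res <- .stage("mars", {
      spots <- sel_ab$spot_id
      if (length(spots) < 1) stop("no selected spots to model on")
      gels <- .gels_for(gs, channel = "Asc+")
      Xf <- t(log2(pmax(gs$volumes[spots, gels, drop = FALSE],
                        .Machine$double.xmin)))
      yf <- as.integer(gs$gel_meta$group[match(gels, gs$gel_meta$gel_id)] == "HF")
      schemes <- config$mars_scheme
      lapply(stats::setNames(schemes, schemes), function(sc) {
        mars_validate(Xf, yf, scheme = sc, seed = config$seed,
                      max_bases = min(config$mars_max_bases, length(spots)),
                      penalty = config$mars_penalty)
      })
    })
    if (!is.null(out_dir)) {
      for (sc in names(res)) {
        write_mars_model(res[[sc]]$model, art(paste0("mars_model_", sc, ".json")))
        utils::write.table(res[[sc]]$roc_test, art(paste0("roc_test_", sc, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    report$stages$mars <- lapply(res, function(v) {
      list(auc_train = v$auc_train, auc_test = v$auc_test,
           selected_variables = v$selected_variables)
    })
  }

  if ("verify_table" %in% stages) {
    ver <- .stage("verify_table", {
      fx <- if (is.null(config$fixture)) reference_spot_table()
            else reference_spot_table(config$fixture)
      verify_table_fixture(fx)
    })
    if (!is.null(out_dir)) {
      utils::write.table(ver$rows, art("fixture_verification.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$stages$verify_table <- c(list(pass_rate = ver$pass_rate), ver$extrema)
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, art("run_report.json"))
  report
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  for (s in names(x$stages)) {
    cat(" -", s, "\n")
  }
  invisible(x)
}
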