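# Pipeline orchestration: simulate -> build -> metrics -> compare -> nbs
# -> clinical, as one configured, seeded, logged run. Every stochastic
# stage derives its RNG stream from the global seed plus a stage tag, so a
# saved configuration replays to identical outputs.

.RUN_STAGES <- c("simulate", "build", "metrics", "compare", "nbs",
                 "clinical")

.default_config <- function() {
  list(
    out_dir = "morphnet_run",
    seed = 1,
    stages = .RUN_STAGES,
    cohort = list(),           # overrides for cohort_spec()
    build = list(n_grid = 512),
    thresholds = list(s_min = 0.10, s_max = 0.35, s_step = 0.01),
    metrics = list(n_nulls = 100),
    compare = list(n_perm = 10000, fdr_q = 0.05, include_nodal = TRUE),
    nbs = list(f_threshold = 4.64, t_threshold = 2.64, n_perm = 10000,
               use_significant_nodes = TRUE),
    clinical = list(group = "SleET",
                    variables = c("TRS", "PSQI", "onset_age", "duration"),
                    covariates = c("age", "sex", "education", "HAMA",
                                   "HAMD"))
  )
}

#' Build a validated pipeline configuration
#'
#' Unknown keys (top-level or within a section) are rejected before any
#' stage runs; omitted keys take defaults. Configurations round-trip
#' through JSON, so a saved run report replays exactly.
#'
#' @param ... overrides of the default configuration, e.g.
#'   `seed = 7`, `cohort = list(seed = 7, n_rois = 30)`,
#'   `stages = c("simulate", "build")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- .default_config()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (key in names(over)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      bad <- setdiff(names(over[[key]]), c(names(defaults[[key]]),
        if (key == "cohort") names(formals(cohort_spec))))
      if (length(bad)) {
        stop("unknown key(s) in section '", key, "': ",
             paste(bad, collapse = ", "))
      }
      cfg[[key]][names(over[[key]])] <- over[[key]]
    } else {
      cfg[[key]] <- over[[key]]
    }
  }
  bad_stage <- setdiff(cfg$stages, .RUN_STAGES)
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with the [run_config()] structure.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(raw)
}

.log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort, writes all
#' stage outputs under `config$out_dir`, and returns (and writes) a JSON
#' run report with per-stage record counts, seeds and output paths. Any
#' stage failure aborts with a diagnostic naming the stage.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress via [message()].
#' @return the run report, invisibly (a named list).
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "morphnet",
                 version = as.character(utils::packageVersion("morphnet")),
                 seed = config$seed, stages = list(),
                 config = unclass(config))
  stage_env <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible())
    .log_stage(verbose, "[morphnet] stage %s ...", name)
    t0 <- Sys.time()
    rec <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    rec$elapsed_sec <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    report$stages[[name]] <<- rec
  }

  run_stage("simulate", function() {
    co <- config$cohort
    co$seed <- if (!is.null(co$seed)) co$seed else derive_seed(config$seed,
                                                               "simulate")
    spec <- do.call(cohort_spec, co)
    cohort <- generate_cohort(spec)
    dir_ <- file.path(out_dir, "cohort")
    write_cohort(cohort, dir_)
    assign("cohort", cohort, envir = stage_env)
    list(n_subjects = nrow(cohort$table),
         n_rois = length(cohort$roi_names), out = dir_)
  })

  run_stage("build", function() {
    cohort <- get("cohort", envir = stage_env)
    dir_ <- file.path(out_dir, "networks")
    dir.create(dir_, showWarnings = FALSE)
    networks <- lapply(cohort$samples, build_network,
                       n_grid = config$build$n_grid)
    for (nw in networks) {
      write_network(nw, file.path(dir_, paste0(nw$subject_id, ".tsv")))
    }
    assign("networks", networks, envir = stage_env)
    list(n_networks = length(networks),
         n_grid = config$build$n_grid, out = dir_)
  })

  run_stage("metrics", function() {
    networks <- get("networks", envir = stage_env)
    tspec <- do.call(threshold_spec, config$thresholds)
    panels <- lapply(networks, sweep_metrics, spec = tspec,
                     n_nulls = config$metrics$n_nulls,
                     seed = derive_seed(config$seed, "metrics"))
    auc <- t(vapply(panels, function(p) {
      c(p$auc_global,
        stats::setNames(as.vector(t(p$auc_nodal)),
                        as.vector(outer(rownames(p$auc_nodal),
                                        colnames(p$auc_nodal),
                                        paste, sep = "|"))))
    }, numeric(length(panels[[1]]$auc_global) +
                 length(panels[[1]]$auc_nodal))))
    rownames(auc) <- vapply(panels, `[[`, "", "subject_id")
    utils::write.table(
      data.frame(subject_id = rownames(auc), auc, check.names = FALSE),
      file.path(out_dir, "auc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    assign("panels", panels, envir = stage_env)
    assign("auc", auc, envir = stage_env)
    list(n_panels = length(panels), n_thresholds = length(tspec$levels),
         out = file.path(out_dir, "auc.tsv"))
  })

  run_stage("compare", function() {
    cohort <- get("cohort", envir = stage_env)
    auc <- get("auc", envir = stage_env)
    if (!isTRUE(config$compare$include_nodal)) {
      auc <- auc[, !grepl("|", colnames(auc), fixed = TRUE), drop = FALSE]
    }
    res <- compare_groups(auc, cohort$table$group,
                          n_perm = config$compare$n_perm,
                          seed = derive_seed(config$seed, "compare"),
                          fdr_q = config$compare$fdr_q)
    utils::write.table(res, file.path(out_dir, "group_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    assign("group_tests", res, envir = stage_env)
    list(n_tests = nrow(res),
         n_significant = sum(res$significant, na.rm = TRUE),
         out = file.path(out_dir, "group_tests.tsv"))
  })

  run_stage("nbs", function() {
    cohort <- get("cohort", envir = stage_env)
    networks <- get("networks", envir = stage_env)
    node_subset <- NULL
    if (isTRUE(config$nbs$use_significant_nodes) &&
        exists("group_tests", envir = stage_env)) {
      gt <- get("group_tests", envir = stage_env)
      sig <- gt$metric[gt$family == "degree" & gt$significant %in% TRUE]
      if (length(sig) >= 2) node_subset <- sub(".*\\|", "", sig)
    }
    cfg <- nbs_config(f_threshold = config$nbs$f_threshold,
                      t_threshold = config$nbs$t_threshold,
                      n_perm = config$nbs$n_perm,
                      node_subset = node_subset)
    res <- nbs_permutation_test(networks, cohort$table$group,
                                contrast = "anova", config = cfg,
                                seed = derive_seed(config$seed, "nbs"))
    utils::write.table(nbs_edge_table(res),
                       file.path(out_dir, "nbs_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_components = length(res$components),
         n_preselected_nodes = length(node_subset),
         out = file.path(out_dir, "nbs_components.tsv"))
  })

  run_stage("clinical", function() {
    cohort <- get("cohort", envir = stage_env)
    auc <- get("auc", envir = stage_env)
    nodal_cols <- grep("|", colnames(auc), fixed = TRUE, value = TRUE)
    target <- paste0("degree|", cohort$spec$trs_target_roi)
    metrics <- unique(c(intersect(target, nodal_cols),
                        utils::head(nodal_cols, 0)))
    if (!length(metrics)) metrics <- utils::head(nodal_cols, 1)
    res <- clinical_correlations(
      auc[, nodal_cols, drop = FALSE], cohort$table,
      group = config$clinical$group, metrics = metrics,
      variables = config$clinical$variables,
      covariate_cols = config$clinical$covariates)
    utils::write.table(res, file.path(out_dir, "clinical_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_correlations = nrow(res),
         out = file.path(out_dir, "clinical_correlations.tsv"))
  })

  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  .log_stage(verbose, "[morphnet] report written to %s", report_path)
  invisible(report)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `extract`, `build`, `metrics`,
#' `compare`, `nbs`, `clinical` and `run` used by the `morphnet` script
#' (see `inst/cli/morphnet`). Options are `--key value` pairs.
#'
#' @param argv character vector of arguments (default
#'   [base::commandArgs()]).
#' @return exit status, invisibly (0 on success).
#' @export
morphnet_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: morphnet <command> [--key value ...]",
    "commands:",
    "  simulate --out DIR [--seed N] [--subjects A,B,C] [--rois N]",
    "  extract  --gm FILE --atlas FILE --out FILE",
    "  build    --samples DIR --out DIR [--grid-points N]",
    "  metrics  --networks DIR --out DIR [--smin S] [--smax S]",
    "           [--sstep S] [--nulls N] [--seed N]",
    "  compare  --auc FILE --cohort FILE --out FILE [--nperm N]",
    "           [--fdr Q] [--seed N]",
    "  nbs      --networks DIR --cohort FILE --out FILE",
    "           [--f-threshold F] [--t-threshold T] [--nperm N] [--seed N]",
    "  clinical --auc FILE --cohort FILE --out FILE [--group G]",
    "  run      --config FILE [--seed N] [--stages a,b,c] [--out DIR]",
    sep = "\n")
  if (!length(argv)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- list()
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!grepl("^--", key) || i == length(rest)) {
      stop("malformed option near '", key, "'")
    }
    opts[[sub("^--", "", key)]] <- rest[i + 1]
    i <- i + 2
  }
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required option --", k)
    opts[[k]]
  }
  opt_num <- function(k, default) {
    if (is.null(opts[[k]])) default else as.numeric(opts[[k]])
  }
  switch(cmd,
    simulate = {
      sizes <- if (is.null(opts$subjects)) c(45, 59, 66) else {
        as.integer(strsplit(opts$subjects, ",")[[1]])
      }
      spec <- cohort_spec(
        group_sizes = stats::setNames(sizes, c("SleET", "NorET", "HC")),
        n_rois = opt_num("rois", 116), seed = opt_num("seed", 1))
      write_cohort(generate_cohort(spec), need("out"))
    },
    extract = {
      rs <- extract_roi_samples(need("gm"), need("atlas"))
      write_roi_table(rs, need("out"))
    },
    build = {
      dir_ <- need("samples")
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      files <- list.files(dir_, pattern = "\\.tsv$", full.names = TRUE)
      files <- files[basename(files) != "cohort.tsv"]
      for (f in files) {
        nw <- build_network(read_roi_table(f),
                            n_grid = opt_num("grid-points", 512))
        write_network(nw, file.path(out, basename(f)))
      }
    },
    metrics = {
      files <- list.files(need("networks"), pattern = "\\.tsv$",
                          full.names = TRUE)
      tspec <- threshold_spec(opt_num("smin", 0.10), opt_num("smax", 0.35),
                              opt_num("sstep", 0.01))
      out <- need("out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      auc_rows <- list()
      for (f in files) {
        p <- sweep_metrics(read_network(f), spec = tspec,
                           n_nulls = opt_num("nulls", 100),
                           seed = opt_num("seed", 1))
        long <- data.frame(subject = p$subject_id,
                           threshold = p$global$threshold,
                           p$global[, -1], check.names = FALSE)
        utils::write.table(long,
                           file.path(out, paste0(p$subject_id,
                                                 "_global.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        auc_rows[[p$subject_id]] <- c(
          p$auc_global,
          stats::setNames(as.vector(t(p$auc_nodal)),
                          as.vector(outer(rownames(p$auc_nodal),
                                          colnames(p$auc_nodal),
                                          paste, sep = "|"))))
      }
      auc <- do.call(rbind, auc_rows)
      utils::write.table(
        data.frame(subject_id = rownames(auc), auc, check.names = FALSE),
        file.path(out, "auc.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    },
    compare = {
      auc_df <- utils::read.delim(need("auc"), check.names = FALSE)
      cohort <- utils::read.delim(need("cohort"))
      auc <- as.matrix(auc_df[, -1, drop = FALSE])
      rownames(auc) <- auc_df[[1]]
      res <- compare_groups(auc,
                            cohort$group[match(rownames(auc),
                                               cohort$subject_id)],
                            n_perm = opt_num("nperm", 10000),
                            seed = opt_num("seed", 1),
                            fdr_q = opt_num("fdr", 0.05))
      utils::write.table(res, need("out"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    nbs = {
      files <- list.files(need("networks"), pattern = "\\.tsv$",
                          full.names = TRUE)
      networks <- lapply(files, read_network)
      ids <- vapply(networks, `[[`, "", "subject_id")
      cohort <- utils::read.delim(need("cohort"))
      res <- nbs_permutation_test(
        networks, cohort$group[match(ids, cohort$subject_id)],
        config = nbs_config(f_threshold = opt_num("f-threshold", 4.64),
                            t_threshold = opt_num("t-threshold", 2.64),
                            n_perm = opt_num("nperm", 10000)),
        seed = opt_num("seed", 1))
      utils::write.table(nbs_edge_table(res), need("out"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    clinical = {
      auc_df <- utils::read.delim(need("auc"), check.names = FALSE)
      cohort <- utils::read.delim(need("cohort"))
      auc <- as.matrix(auc_df[, -1, drop = FALSE])
      rownames(auc) <- auc_df[[1]]
      cohort <- cohort[match(rownames(auc), cohort$subject_id), ]
      nodal <- grep("|", colnames(auc), fixed = TRUE, value = TRUE)
      res <- clinical_correlations(
        auc[, nodal, drop = FALSE], cohort,
        group = if (is.null(opts$group)) "SleET" else opts$group)
      utils::write.table(res, need("out"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    run = {
      cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else {
        run_config()
      }
      if (!is.null(opts$seed)) cfg$seed <- as.numeric(opts$seed)
      if (!is.null(opts$stages)) {
        cfg$stages <- strsplit(opts$stages, ",")[[1]]
        cfg <- run_config(unclass(cfg))
      }
      if (!is.null(opts$out)) cfg$out_dir <- opts$out
      run_pipeline(cfg)
    },
    {
      message(usage)
      stop("unknown command: ", cmd)
    }
  )
  invisible(0L)
}
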