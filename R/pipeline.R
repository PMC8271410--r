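#' Default pipeline configuration
#'
#' Known keys only; unknown keys in `overrides` are rejected so typos fail
#' loudly. The resolved configuration is written next to every run's
#' outputs.
#'
#' @param overrides Named list of configuration overrides.
#' @return Named list of resolved settings.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    stages = c("score", "screen", "doe", "bonds"),
    scores = synergy_fixture("table1_scores.csv"),
    predictions = synergy_fixture("table3_predictions.csv"),
    env = synergy_fixture("table4_env.csv"),
    doe_responses = synergy_fixture("table6_responses.csv"),
    interactions = synergy_fixture("table7_interactions.csv"),
    template = "BDEs-3",
    tie_policy = "average",
    weight_mode = "own_docking_scores",
    compare = c("BDEs-3", "BDEs-3-19"),
    hydrophobic_set = HYDROPHOBIC_RESIDUES,
    grid_spacing = 2.0, grid_margin = 4.0,
    steric_cutoff = 30, min_sigma = 2.0,
    seed = 1L,
    out_dir = NULL)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, overrides)
}

write_report_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the pipeline stages end to end
#'
#' Executes the requested stages in the fixed order score -> screen ->
#' doe -> bonds on the configured inputs (packaged worked tables by
#' default), collecting every stage report into one bundle and, when
#' `out_dir` is set, writing CSV/JSON reports plus the resolved
#' configuration and a human-readable summary.
#'
#' @param config List from [pipeline_config()].
#' @param quiet Suppress the stderr stage log.
#' @return Named list of stage reports (invisibly when writing files).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  log_msg <- function(stage, ...) if (!quiet)
    message("[", stage, "] ", ...)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(config = config)
  summary_lines <- character()

  for (stage in config$stages) {
    res <- tryCatch(switch(stage,
      score = {
        log_msg("score", "queuing scores from ", config$scores)
        tab <- read_score_table(config$scores)
        cs <- composite_scores(tab, weight_mode = config$weight_mode,
                               tie_policy = config$tie_policy)
        write_report_csv(cs, out_dir, "composite_scores.csv")
        summary_lines <- c(summary_lines, sprintf(
          "score: %d molecules; top CS = %s (%.3f)", nrow(cs),
          cs$molecule_id[which.max(cs$CS)], max(cs$CS)))
        cs
      },
      screen = {
        log_msg("screen", "derivative screens")
        fun <- functional_screen(read_predictions(config$predictions),
                                 config$template)
        env <- environmental_screen(read_env_profiles(config$env),
                                    config$template)
        write_report_csv(env$ledger, out_dir, "environmental_ledger.csv")
        summary_lines <- c(summary_lines, sprintf(
          "screen: %d derivatives pass all QSAR models; %d pass every environmental criterion (%s)",
          length(fun), length(env$selected),
          paste(env$selected, collapse = ", ")))
        list(functional = fun, environmental = env)
      },
      doe = {
        log_msg("doe", "regulatory scheme evaluation from ",
                config$doe_responses)
        doe <- read_doe_responses(config$doe_responses)
        ev <- scheme_improvements(doe$responses)
        write_report_csv(ev$table, out_dir, "scheme_evaluation.csv")
        summary_lines <- c(summary_lines, sprintf(
          "doe: %d synergy-flagged scheme(s); best scheme = %s",
          sum(ev$table$synergy), ev$best))
        ev
      },
      bonds = {
        log_msg("bonds", "contact statistics for ",
                paste(config$compare, collapse = " vs "))
        ints <- read_interactions(config$interactions)
        per <- lapply(split(ints, list(ints$ligand, ints$receptor),
                            drop = TRUE),
                      bond_stats, hydrophobic_set = config$hydrophobic_set)
        cmp <- lapply(unique(ints$receptor), function(rec) {
          b <- per[[paste(config$compare[1], rec, sep = ".")]]
          a <- per[[paste(config$compare[2], rec, sep = ".")]]
          data.frame(receptor = rec,
                     mean_before = b$mean_distance,
                     mean_after = a$mean_distance,
                     decrease_pct = length_change(b, a),
                     halogen_before = b$halogen_bonds,
                     halogen_after = a$halogen_bonds)
        })
        cmp <- do.call(rbind, cmp)
        write_report_csv(cmp, out_dir, "bond_comparison.csv")
        summary_lines <- c(summary_lines, sprintf(
          "bonds: mean contact distance decreased %.2f%% (%s) and %.2f%% (%s)",
          cmp$decrease_pct[1], cmp$receptor[1],
          cmp$decrease_pct[2], cmp$receptor[2]))
        list(stats = per, comparison = cmp)
      },
      stop("unknown stage: ", stage)),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    report[[stage]] <- res
  }

  if (!is.null(out_dir)) {
    cfg_out <- config
    cfg_out$stages <- as.list(cfg_out$stages)
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  report$summary <- summary_lines
  invisible(report)
}

# --- command-line interface -------------------------------------------------

cli_usage <- "usage: synergy <command> [options]

commands:
  score          queuing scores from a docking score table
                   --in PATH [--out PATH] [--weight-mode own|fixed]
                   [--ties average|min|ordinal]
  screen         functional + environmental derivative screens
                   --predictions PATH --env PATH [--template ID]
  doe-factorial  regulatory scheme evaluation from a response table
                   --responses PATH
  doe-taguchi    L12 factor-effect ranking from a response table
                   --responses PATH --system NAME
  qsar-fit       fit a CoMFA-style PLS model on aligned atom-table CSVs
                   --structures DIR --activity PATH [--column CS]
                   [--seed N] --out model.json
  qsar-predict   predict activities for new structures
                   --model model.json --structures DIR
  bonds          contact statistics and before/after comparison
                   --in PATH [--compare BEFORE:AFTER]
  simulate       synthetic inputs: scores|doe  --seed N --out DIR
  run            full pipeline on the packaged tables  [--out DIR]
"

parse_cli <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3))
      if (i == length(args) || startsWith(args[[i + 1L]], "--"))
        stop("option ", a, " needs a value")
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(pos = pos, opts = opts)
}

#' Command-line entry point
#'
#' Dispatches the `synergy` subcommands (see `inst/cli/synergy` for the
#' Rscript launcher). Returns the exit status instead of calling `quit()`
#' so it is testable in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 = success).
#' @export
synergy_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) { cat(cli_usage); return(invisible(1L)) }
    p <- parse_cli(args[-1]); o <- p$opts
    cmd <- args[[1]]
    switch(cmd,
      score = {
        tab <- read_score_table(o$`in` %||% stop("--in required"))
        cs <- composite_scores(tab,
                               weight_mode = o$weight_mode %||% "own_docking_scores",
                               tie_policy = o$ties %||% "average")
        if (!is.null(o$out)) utils::write.csv(cs, o$out, row.names = FALSE)
        else print(utils::head(cs[order(-cs$CS), ], 10))
      },
      screen = {
        fun <- functional_screen(read_predictions(o$predictions),
                                 o$template %||% "BDEs-3")
        env <- environmental_screen(read_env_profiles(o$env),
                                    o$template %||% "BDEs-3")
        cat("functional pass:", paste(fun, collapse = ", "), "\n")
        cat("environmental pass:", paste(env$selected, collapse = ", "), "\n")
      },
      `doe-factorial` = {
        doe <- read_doe_responses(o$responses)
        print(scheme_improvements(doe$responses))
      },
      `doe-taguchi` = {
        doe <- read_doe_responses(o$responses)
        sys <- o$system %||% setdiff(names(doe$responses), "run")[1]
        resp <- doe$responses[doe$responses$run != 0, ]
        snr <- vapply(abs(resp[[sys]]), snr_larger_is_better, numeric(1))
        design <- as.matrix(doe$design[doe$design$run != 0,
                                       setdiff(names(doe$design), "run")])
        print(factor_effects(design, snr))
      },
      `qsar-fit` = {
        files <- list.files(o$structures %||% stop("--structures required"),
                            pattern = "\\.csv$", full.names = TRUE)
        if (length(files) < 8L) stop("need at least 8 structure files")
        conf <- read_conformers(files)
        act <- read_score_table(o$activity %||% stop("--activity required"))
        col <- o$column %||% "CS"
        if (!col %in% names(act)) stop("activity column not found: ", col)
        y <- stats::setNames(act[[col]], act$molecule_id)
        f <- compute_fields(conf)
        ds <- qsar_dataset(f, y)
        train <- split_train_test(ds$y, seed = as.integer(o$seed %||% 1))
        m <- fit_pls_loo(ds, train = which(train))
        rp <- r2_pred(ds$y[!train],
                      predict(m, ds$X[!train, , drop = FALSE]), m$ybar_train)
        print(m)
        print(quality_report(m, r2pred = rp))
        write_pls_model(m, o$out %||% "model.json", grid = f$grid,
                        probe = default_probe())
      },
      `qsar-predict` = {
        m <- read_pls_model(o$model %||% stop("--model required"))
        files <- list.files(o$structures %||% stop("--structures required"),
                            pattern = "\\.csv$", full.names = TRUE)
        pred <- predict_structures(m, read_conformers(files))
        utils::write.csv(data.frame(molecule_id = names(pred),
                                    predicted = unname(pred)),
                         o$out %||% stdout(), row.names = FALSE)
      },
      bonds = {
        ints <- read_interactions(o$`in` %||% stop("--in required"))
        cmp <- strsplit(o$compare %||% "BDEs-3:BDEs-3-19", ":")[[1]]
        for (rec in unique(ints$receptor)) {
          b <- bond_stats(ints[ints$ligand == cmp[1] & ints$receptor == rec, ])
          a <- bond_stats(ints[ints$ligand == cmp[2] & ints$receptor == rec, ])
          cat(sprintf("%s: mean %.2f -> %.2f A (decrease %.2f%%), halogen bonds %d -> %d\n",
                      rec, b$mean_distance, a$mean_distance,
                      length_change(b, a), b$halogen_bonds, a$halogen_bonds))
        }
      },
      simulate = {
        what <- p$pos[1] %||% "scores"
        seed <- as.integer(o$seed %||% 1)
        dir.create(o$out %||% ".", showWarnings = FALSE, recursive = TRUE)
        if (what == "scores") {
          utils::write.csv(gen_score_table(seed = seed),
                           file.path(o$out %||% ".", "scores.csv"),
                           row.names = FALSE)
        } else if (what == "doe") {
          d <- full_factorial(c("A", "D", "F", "G"))
          eff <- c(A = -20, D = -5, F = -8, G = -3)
          utils::write.csv(gen_doe_responses(d, eff, seed = seed),
                           file.path(o$out %||% ".", "doe_responses.csv"),
                           row.names = FALSE)
        } else stop("unknown simulate target: ", what)
      },
      run = {
        cfg <- pipeline_config(if (!is.null(o$out)) list(out_dir = o$out)
                               else list())
        rep <- run_pipeline(cfg)
        cat(rep$summary, sep = "\n")
      },
      { cat(cli_usage); stop("unknown command: ", cmd) })
    0L
  }, error = function(e) {
    message("synergy: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
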