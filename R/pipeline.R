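# Orchestration: config-driven pipeline (normalize -> GA select ->
# ANN train/validate -> report) with seeded, byte-reproducible
# artifacts, plus the command-line entry point.

#' Build a pipeline configuration
#'
#' Exactly one of `input` (paths to descriptor and PK CSV files) or
#' `synthetic` (a [synthetic_spec()]) must be supplied.
#'
#' @param input List with `descriptors` and `pk` CSV paths, or `NULL`.
#' @param synthetic A [synthetic_spec()], or `NULL`.
#' @param ga A [ga_control()].
#' @param ann An [ann_control()].
#' @param n_repeats,n_train Validation settings (see
#'   [repeated_subsampling_validation()]).
#' @param missing_policy Passed to [handle_missing()].
#' @param seed Global integer seed.
#' @return A list of class `qspkr_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            ga = ga_control(), ann = ann_control(),
                            n_repeats = 10L, n_train = NULL,
                            missing_policy = "drop_columns",
                            seed = 1L) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be given")
  if (!is.null(input))
    stopifnot(is.list(input), !is.null(input$descriptors), !is.null(input$pk))
  structure(list(input = input, synthetic = synthetic, ga = ga, ann = ann,
                 n_repeats = as.integer(n_repeats), n_train = n_train,
                 missing_policy = missing_policy, seed = as.integer(seed)),
            class = "qspkr_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `n_repeats`, `n_train`,
#' `missing_policy`, and sections `input` (`descriptors:`, `pk:`),
#' `synthetic`, `ga` and `ann`, whose entries map one-to-one to the
#' arguments of [synthetic_spec()], [ga_control()] and
#' [ann_control()].
#'
#' @param path YAML file path.
#' @return A `qspkr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list(
    input = y$input,
    synthetic = if (!is.null(y$synthetic))
      do.call(synthetic_spec, y$synthetic),
    ga = do.call(ga_control, y$ga %||% list()),
    ann = do.call(ann_control, y$ann %||% list()),
    n_repeats = y$n_repeats %||% 10L,
    n_train = y$n_train,
    missing_policy = y$missing_policy %||% "drop_columns",
    seed = y$seed %||% 1L)
  do.call(pipeline_config, args)
}

# Polynomial rolling hash over the deparsed config: a stable
# fingerprint stamped into every artifact so outputs of different
# configs are identifiable.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes load/simulate -> normalize -> GA select -> ANN validate ->
#' final train, writing `selection.json`, `model_final.json`,
#' `evaluation.json`, `predictions.csv` and `run.log` into `out_dir`.
#' Every JSON artifact is stamped with the config hash and seed;
#' re-running with an identical config and seed reproduces
#' byte-identical JSON artifacts.  If a stage fails, a `FAILED` marker
#' file naming the stage is left in `out_dir` and the error is
#' re-thrown.
#'
#' @param config A `qspkr_pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return The fitted [qspkr] object, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "qspkr_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("qspkr pipeline | config %s | seed %d | started %s\n",
              hash, config$seed, format(Sys.time())), file = logf)
  say <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  stage <- "load_data"
  on.exit(writeLines(paste("stage:", stage),
                     file.path(out_dir, "FAILED")), add = TRUE)

  data <- if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    if (is.null(spec$seed)) spec$seed <- derive_seed(config$seed, 0L)
    synth <- generate_dataset(spec)
    say("simulated %d x %d dataset (%.1f%% of pairs within epsilon)",
        nrow(synth$data$X), ncol(synth$data$X),
        100 * synth$truth$fraction_within_epsilon)
    synth$data
  } else {
    raw_x <- handle_missing(read_descriptor_table(config$input$descriptors),
                            config$missing_policy)
    raw_pk <- read_pk_table(config$input$pk)
    say("read %d compounds, %d descriptors", length(raw_x$compound_ids),
        length(raw_x$column_names))
    minmax_normalize(raw_x, raw_pk)
  }

  stage <- "ga_select"
  ga <- config$ga
  if (is.null(ga$seed)) ga$seed <- derive_seed(config$seed, 1L)
  sel <- run_ga(data, ga)
  say("GA: %d descriptors after %d generations (%s)",
      length(sel$selected), sel$generations, sel$termination)
  write_json_artifact(list(
    selected_indices = sel$selected,
    selected_names = sel$selected_names,
    fitness_trajectory = sel$fitness_trajectory,
    gene_count_trajectory = sel$gene_count_trajectory,
    generations = sel$generations,
    termination_reason = sel$termination,
    seed = ga$seed), hash, config$seed,
    file.path(out_dir, "selection.json"))

  stage <- "validate"
  val <- repeated_subsampling_validation(data, sel$selected, config$ann,
                                         n_repeats = config$n_repeats,
                                         n_train = config$n_train,
                                         seed = derive_seed(config$seed, 2L))
  say("validation: pooled R %.4f RMSE %.4g NRMSE %.4f",
      val$aggregate$R, val$aggregate$RMSE, val$aggregate$NRMSE)
  write_json_artifact(list(
    n_repeats = val$n_repeats, n_train = val$n_train, n_test = val$n_test,
    per_repeat = val$per_repeat,
    aggregate = val$aggregate[c("R", "pearson_r", "RMSE", "NRMSE")],
    mean = as.list(val$aggregate$mean), sd = as.list(val$aggregate$sd),
    pk_name = val$pk_name, pk_unit = val$pk_unit),
    hash, config$seed, file.path(out_dir, "evaluation.json"))
  utils::write.csv(val$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  stage <- "final_train"
  ann <- config$ann
  if (is.null(ann$seed)) ann$seed <- derive_seed(config$seed, 3L)
  final <- train_ann(init_network(length(sel$selected), ann),
                     data$X[, sel$selected, drop = FALSE], data$dp, ann)
  write_json_artifact(ann_to_list(final), hash, config$seed,
                      file.path(out_dir, "model_final.json"))
  say("done")
  on.exit()  # all stages succeeded: no FAILED marker
  fit <- structure(list(data = data, selection = sel, validation = val,
                        final_model = final, seed = config$seed,
                        call = sys.call()),
                   class = "qspkr")
  invisible(fit)
}

write_json_artifact <- function(x, hash, seed, path) {
  x <- c(list(config_hash = hash, global_seed = seed), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic descriptor/PK fixture as
#' CSV plus the ground truth as JSON), `select` (GA selection only),
#' `evaluate` (validation for a given selection), `run` (full
#' pipeline).  Flags: `--config <yaml>`, `--seed <int>`, `--out <dir>`,
#' `--selection <selection.json>` (for `evaluate`), `--verbose`.
#' Intended to be called from a wrapper script as
#' `quit(status = cli_main(commandArgs(TRUE)))`; see
#' `system.file("cli", "qspkr", package = "qspkr")`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 1 on error (with a message
#'   on stderr).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: qspkr <simulate|select|evaluate|run> [--config cfg.yaml]",
    "[--seed N] [--out DIR] [--selection selection.json] [--verbose]")
  tryCatch({
    if (length(argv) < 1L) stop(usage, call. = FALSE)
    cmd <- argv[[1L]]
    opts <- parse_cli_flags(argv[-1L], usage)
    if (!cmd %in% c("simulate", "select", "evaluate", "run"))
      stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
    out <- opts$out %||% "qspkr_out"
    config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
              else pipeline_config(synthetic = synthetic_spec(),
                                   seed = opts$seed %||% 1L)
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)

    if (cmd == "simulate") {
      spec <- config$synthetic %||% synthetic_spec()
      spec$seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
                   else spec$seed %||% config$seed
      synth <- generate_dataset(spec)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_qspkr_csv(synth$raw$descriptors,
                      file.path(out, "descriptors.csv"))
      write_qspkr_csv(synth$raw$pk, file.path(out, "pk.csv"),
                      unit = spec$pk_unit)
      jsonlite::write_json(synth$truth, file.path(out, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (isTRUE(opts$verbose)) message("fixture written to ", out)
    } else if (cmd == "select") {
      data <- pipeline_load_data(config)
      ga <- config$ga
      if (is.null(ga$seed)) ga$seed <- derive_seed(config$seed, 1L)
      sel <- run_ga(data, ga)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_json_artifact(list(
        selected_indices = sel$selected,
        selected_names = sel$selected_names,
        fitness_trajectory = sel$fitness_trajectory,
        generations = sel$generations,
        termination_reason = sel$termination, seed = ga$seed),
        config_hash(config), config$seed,
        file.path(out, "selection.json"))
      if (isTRUE(opts$verbose))
        message(length(sel$selected), " descriptors selected")
    } else if (cmd == "evaluate") {
      if (is.null(opts$selection))
        stop("evaluate needs --selection selection.json", call. = FALSE)
      selected <- jsonlite::read_json(opts$selection,
                                      simplifyVector = TRUE)$selected_indices
      data <- pipeline_load_data(config)
      val <- repeated_subsampling_validation(data, selected, config$ann,
                                             n_repeats = config$n_repeats,
                                             n_train = config$n_train,
                                             seed = derive_seed(config$seed, 2L))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_json_artifact(list(
        n_repeats = val$n_repeats, per_repeat = val$per_repeat,
        aggregate = val$aggregate[c("R", "pearson_r", "RMSE", "NRMSE")]),
        config_hash(config), config$seed,
        file.path(out, "evaluation.json"))
      utils::write.csv(val$predictions, file.path(out, "predictions.csv"),
                       row.names = FALSE)
    } else {
      run_pipeline(config, out)
    }
    0L
  }, error = function(e) {
    message("qspkr: ", conditionMessage(e))
    1L
  })
}

parse_cli_flags <- function(args, usage) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--verbose") { opts$verbose <- TRUE; i <- i + 1L; next }
    if (!a %in% c("--config", "--seed", "--out", "--selection"))
      stop("unknown flag '", a, "'\n", usage, call. = FALSE)
    if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
    opts[[sub("^--", "", a)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

pipeline_load_data <- function(config) {
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    if (is.null(spec$seed)) spec$seed <- derive_seed(config$seed, 0L)
    generate_dataset(spec)$data
  } else {
    raw_x <- handle_missing(read_descriptor_table(config$input$descriptors),
                            config$missing_policy)
    minmax_normalize(raw_x, read_pk_table(config$input$pk))
  }
}
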