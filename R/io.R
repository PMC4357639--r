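#' Read a wide-format dataset CSV
#'
#' Strict reader for the package's tabular interchange format: a header
#' exactly `y1,y2,y3,group`, numeric complete outcome cells, and `group`
#' coded strictly as 0 or 1.  Violations raise input errors naming the
#' offending row.
#'
#' @param path Path to the CSV file.
#' @return A [longitudinal_data] object.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- c("y1", "y2", "y3", "group")
  if (!identical(names(raw), expected)) {
    input_error(sprintf("header must be exactly `%s`, found `%s`",
                        paste(expected, collapse = ","),
                        paste(names(raw), collapse = ",")))
  }
  if (nrow(raw) == 0) input_error("dataset has no rows")
  for (i in seq_len(nrow(raw))) {
    for (col in expected) {
      cell <- trimws(raw[i, col])
      if (!nzchar(cell) || is.na(cell)) {
        input_error(sprintf("missing value in column `%s`, row %d (complete cases required)", col, i))
      }
      if (is.na(suppressWarnings(as.numeric(cell)))) {
        input_error(sprintf("non-numeric value `%s` in column `%s`, row %d", cell, col, i))
      }
    }
    if (!trimws(raw[i, "group"]) %in% c("0", "1")) {
      input_error(sprintf("`group` must be 0 or 1, found `%s` in row %d",
                          trimws(raw[i, "group"]), i))
    }
  }
  y <- as.matrix(vapply(raw[c("y1", "y2", "y3")], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) y <- matrix(y, nrow = 1)
  longitudinal_data(y, as.integer(raw$group))
}

#' Write a dataset to the wide CSV format
#'
#' @param data A [longitudinal_data] object.
#' @param path Output path.
#' @export
write_dataset_csv <- function(data, path) {
  if (!inherits(data, "longitudinal_data")) {
    input_error("`data` must be a longitudinal_data object")
  }
  df <- data.frame(data$outcomes, group = data$group)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    input_error(sprintf("unknown key(s) in %s: %s", where,
                        paste(bad, collapse = ", ")))
  }
  invisible()
}

num_field <- function(x, nm, default, where) {
  v <- x[[nm]]
  if (is.null(v)) return(default)
  if (!is.numeric(v) || length(v) < 1) {
    input_error(sprintf("field `%s` in %s must be numeric", nm, where))
  }
  as.numeric(v)
}

priors_from_config <- function(lst) {
  pr <- default_priors()
  if (is.null(lst)) return(pr)
  check_keys(lst, c("structural", "variances"), "priors")
  check_keys(lst$structural, structural_names(), "priors$structural")
  check_keys(lst$variances, variance_names(), "priors$variances")
  for (nm in names(lst$structural)) {
    spec <- lst$structural[[nm]]
    check_keys(spec, c("mean", "variance"), sprintf("priors$structural$%s", nm))
    args <- list(num_field(spec, "mean", 0, nm), num_field(spec, "variance", 1e10, nm))
    pr$structural[[nm]] <- do.call(normal_prior, args)
  }
  for (nm in names(lst$variances)) {
    spec <- lst$variances[[nm]]
    check_keys(spec, c("shape", "scale"), sprintf("priors$variances$%s", nm))
    pr$variances[[nm]] <- inv_gamma_prior(num_field(spec, "shape", -1, nm),
                                          num_field(spec, "scale", 0, nm))
  }
  prior_spec(pr$structural, pr$variances)
}

sampler_from_config <- function(lst, seed_default = 1) {
  if (is.null(lst)) lst <- list()
  check_keys(lst, c("n_iterations", "burn_in_fraction", "seed", "point_estimate_rule"),
             "sampler")
  rule <- lst$point_estimate_rule
  if (is.null(rule)) rule <- "median"
  sampler_config(n_iterations = num_field(lst, "n_iterations", 10000, "sampler"),
                 burn_in_fraction = num_field(lst, "burn_in_fraction", 0.5, "sampler"),
                 seed = num_field(lst, "seed", seed_default, "sampler"),
                 point_estimate_rule = rule)
}

population_from_config <- function(lst) {
  if (is.null(lst)) return(default_population())
  check_keys(lst, parameter_names(), "population")
  base <- unclass(default_population())
  for (nm in names(lst)) base[[nm]] <- num_field(lst, nm, base[[nm]], "population")
  do.call(parameter_set, base[parameter_names()])
}

config_commands <- function() {
  c("simulate", "fit-ml", "fit-bayes", "mc-study", "sensitivity", "diagnose")
}

#' Parse and validate a run configuration
#'
#' Accepts a JSON or YAML document (as text or a file path), validates it
#' against the schema of the given subcommand, rejects unknown keys, and
#' fills every default explicitly.  Numeric defaults follow the study
#' conventions: 10,000 iterations with half burn-in, Normal(0, 1e10)
#' structural priors, IG(-1, 0) variance priors, the simulation-design
#' population, and the printed hyperparameter grids.
#'
#' @param text JSON or YAML document as a single string (or the parsed
#'   list).
#' @param command One of `simulate`, `fit-ml`, `fit-bayes`, `mc-study`,
#'   `sensitivity`, `diagnose`.
#' @param path Alternatively, a file to read the document from.
#' @return Object of class `run_config`.
#' @export
parse_config <- function(text = NULL, command, path = NULL) {
  command <- match.arg(command, config_commands())
  if (!is.null(path)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lst <- if (is.list(text)) {
    text
  } else if (is.null(text) || !nzchar(trimws(text))) {
    list()
  } else if (grepl("^\\s*[{\\[]", text)) {
    jsonlite::fromJSON(text, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(text)
  }
  if (is.null(lst)) lst <- list()

  common <- c("seed", "out", "log_level")
  cfg <- list(command = command,
              seed = as.integer(num_field(lst, "seed", 1, command)),
              out = if (is.null(lst$out)) NULL else as.character(lst$out),
              log_level = if (is.null(lst$log_level)) "info" else as.character(lst$log_level))

  if (command == "simulate") {
    check_keys(lst, c(common, "population", "n", "group_allocation", "n_reps"), command)
    cfg$population <- population_from_config(lst$population)
    cfg$n <- num_field(lst, "n", 8, command)
    cfg$group_allocation <- num_field(lst, "group_allocation", 0.5, command)
    cfg$n_reps <- num_field(lst, "n_reps", 1, command)
  } else if (command == "fit-ml") {
    check_keys(lst, c(common, "data"), command)
    cfg$data <- if (is.null(lst$data)) NULL else as.character(lst$data)
  } else if (command == "fit-bayes") {
    check_keys(lst, c(common, "data", "priors", "sampler", "draws_out"), command)
    cfg$data <- if (is.null(lst$data)) NULL else as.character(lst$data)
    cfg$priors <- priors_from_config(lst$priors)
    cfg$sampler <- sampler_from_config(lst$sampler, seed_default = cfg$seed)
    cfg$draws_out <- if (is.null(lst$draws_out)) NULL else as.character(lst$draws_out)
  } else if (command == "mc-study") {
    check_keys(lst, c(common, "population", "n", "group_allocation", "n_reps",
                      "estimator", "priors", "sampler", "batch_size"), command)
    cfg$population <- population_from_config(lst$population)
    cfg$n <- num_field(lst, "n", 8, command)
    cfg$group_allocation <- num_field(lst, "group_allocation", 0.5, command)
    cfg$n_reps <- num_field(lst, "n_reps", 1000, command)
    est <- if (is.null(lst$estimator)) "ml" else as.character(lst$estimator)
    if (!est %in% c("ml", "bayes")) input_error("`estimator` must be \"ml\" or \"bayes\"")
    cfg$estimator <- est
    cfg$priors <- priors_from_config(lst$priors)
    cfg$sampler <- sampler_from_config(lst$sampler, seed_default = cfg$seed)
    cfg$batch_size <- num_field(lst, "batch_size", 250, command)
  } else if (command == "sensitivity") {
    check_keys(lst, c(common, "data", "mu0_grid", "var0_grid", "priors", "sampler"), command)
    cfg$data <- if (is.null(lst$data)) NULL else as.character(lst$data)
    cfg$mu0_grid <- num_field(lst, "mu0_grid", c(5, 0, -5, -10), command)
    cfg$var0_grid <- num_field(lst, "var0_grid",
                               c(1e10, 1000, 100, 50, 20, 10, 5, 3, 1), command)
    cfg$priors <- priors_from_config(lst$priors)
    cfg$sampler <- sampler_from_config(lst$sampler, seed_default = cfg$seed)
  } else if (command == "diagnose") {
    check_keys(lst, c(common, "draws", "threshold_multiplier"), command)
    cfg$draws <- if (is.null(lst$draws)) NULL else as.character(lst$draws)
    cfg$threshold_multiplier <- num_field(lst, "threshold_multiplier", 50, command)
  }
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration back to a plain list
#'
#' Inverse of [parse_config()]: `parse_config(config_to_list(cfg),
#' cfg$command)` reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @return A plain named list suitable for [jsonlite::toJSON()] or
#'   [yaml::as.yaml()].
#' @export
config_to_list <- function(cfg) {
  out <- list(seed = cfg$seed, out = cfg$out, log_level = cfg$log_level)
  if (!is.null(cfg$population)) {
    out$population <- lapply(unclass(cfg$population)[parameter_names()], as.numeric)
  }
  for (nm in c("n", "group_allocation", "n_reps", "data", "estimator",
               "batch_size", "mu0_grid", "var0_grid", "draws",
               "threshold_multiplier", "draws_out")) {
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  }
  if (!is.null(cfg$priors)) {
    out$priors <- list(
      structural = lapply(cfg$priors$structural, function(p) {
        list(mean = p$mean, variance = p$variance)
      }),
      variances = lapply(cfg$priors$variances, function(p) {
        list(shape = p$shape, scale = p$scale)
      }))
  }
  if (!is.null(cfg$sampler)) {
    out$sampler <- list(n_iterations = cfg$sampler$n_iterations,
                        burn_in_fraction = cfg$sampler$burn_in_fraction,
                        seed = cfg$sampler$seed,
                        point_estimate_rule = cfg$sampler$point_estimate_rule)
  }
  out[!vapply(out, is.null, logical(1))]
}
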