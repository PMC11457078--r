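#' Load and validate a run configuration
#'
#' Reads a structured configuration (YAML `.yml`/`.yaml` or JSON `.json`)
#' with optional sections `model`, `environment`, `encounter`,
#' `integrator`, plus top-level `seed` and `output_dir`, validates every
#' field, fills documented defaults, and rejects unknown keys by name. All
#' violations are collected and reported together.
#'
#' @param path path to the configuration file.
#' @return A `run_config` list with elements `model` (`"induced"` or
#'   `"constitutive"`), `params` ([imd_params()]), `A_const`,
#'   `environment` ([environment_spec()] or `NULL`), `encounter_mode`,
#'   `input` (sinusoidal [imd_input]) or `walks` ([walk_config()]),
#'   `integrator`, `seed`, `output_dir`, and the raw parsed list in
#'   `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  known_top <- c("model", "environment", "encounter", "integrator",
                 "seed", "output_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0) {
    note(paste0("unknown top-level keys: ", paste(unknown, collapse = ", ")))
  }
  check_keys <- function(section, allowed) {
    extra <- setdiff(names(raw[[section]]), allowed)
    if (length(extra) > 0) {
      note(paste0("unknown keys in ", section, ": ",
                  paste(extra, collapse = ", ")))
    }
  }

  model_raw <- raw$model %||% list()
  check_keys("model", c("type", "A_const", names(imd_params())))
  model_type <- model_raw$type %||% "induced"
  if (!model_type %in% c("induced", "constitutive")) {
    note("model$type must be 'induced' or 'constitutive'")
  }
  params <- tryCatch({
    args <- model_raw[intersect(names(model_raw), names(imd_params()))]
    do.call(imd_params, args)
  }, error = function(e) {
    note(conditionMessage(e))
    NULL
  })
  A_const <- model_raw$A_const %||% NULL
  if (model_type == "constitutive" &&
      (!is.null(A_const) && (!is.numeric(A_const) || A_const < 0))) {
    note("model$A_const must be a non-negative number")
  }

  env_spec <- NULL
  if (!is.null(raw$environment)) {
    check_keys("environment",
               c("size", "density", "patchiness", "cluster_sd", "seed"))
    env_spec <- tryCatch(
      do.call(environment_spec, raw$environment),
      error = function(e) {
        note(conditionMessage(e))
        NULL
      })
  }

  enc_raw <- raw$encounter %||% list(mode = "sinusoidal")
  check_keys("encounter", c("mode", "omega", "phi", "n_steps", "n_walks",
                            "dt_per_step", "dose", "neighborhood", "seed"))
  enc_mode <- enc_raw$mode %||% "sinusoidal"
  input <- NULL
  walks <- NULL
  if (identical(enc_mode, "sinusoidal")) {
    input <- tryCatch(
      sinusoidal_input(omega = enc_raw$omega %||% 1,
                       phi = enc_raw$phi %||% 0.01),
      error = function(e) {
        note(conditionMessage(e))
        NULL
      })
  } else if (identical(enc_mode, "walk")) {
    walks <- tryCatch(
      walk_config(n_steps = enc_raw$n_steps %||% 5000,
                  n_walks = enc_raw$n_walks %||% 100,
                  dt_per_step = enc_raw$dt_per_step %||% 1,
                  dose = enc_raw$dose %||% 1,
                  neighborhood = enc_raw$neighborhood %||% "von_neumann",
                  seed = enc_raw$seed),
      error = function(e) {
        note(conditionMessage(e))
        NULL
      })
  } else {
    note("encounter$mode must be 'sinusoidal' or 'walk'")
  }

  int_raw <- raw$integrator %||% list()
  check_keys("integrator",
             c("h", "method", "t_end", "record_stride", "clip_negative"))
  integ <- tryCatch(
    integrator_config(h = int_raw$h %||% 0.01,
                      method = int_raw$method %||% "euler",
                      t_end = int_raw$t_end %||% 100,
                      record_stride = int_raw$record_stride %||% 1L,
                      clip_negative = int_raw$clip_negative %||% TRUE),
    error = function(e) {
      note(conditionMessage(e))
      NULL
    })

  seed <- raw$seed %||% NULL
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1)) {
    note("seed must be a single number")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  structure(list(model = model_type, params = params, A_const = A_const,
                 environment = env_spec, encounter_mode = enc_mode,
                 input = input, walks = walks, integrator = integ,
                 seed = seed, output_dir = raw$output_dir %||% ".",
                 raw = raw),
            class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config` (or the raw list it was parsed from).
#' @param path output path; extension selects YAML or JSON.
#' @export
save_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation results to disk
#'
#' Trajectories go to TSV with the fixed header `time f B G R C N L P S
#' A` (constitutive trajectories carry only `B`); fitness grids go to CSV
#' with a JSON provenance sidecar (`<path>.json`); everything else is
#' serialized as JSON. Field order is deterministic.
#'
#' @param x object to write.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.imd_trajectory <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.fitness_grid <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(attr(x, "provenance"), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @export
write_results.imd_opt <- function(x, path) {
  out <- list(strategy = x$strategy, fitness = x$fitness,
              provenance = x$provenance)
  if (x$strategy == "constitutive") {
    out$A <- x$A
    out$curve <- x$curve
  } else {
    out$params <- unclass(x$params)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @export
write_results.default <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a trajectory written by [write_results()]
#'
#' @param path TSV file path.
#' @return An `imd_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  out <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  class(out) <- c("imd_trajectory", class(out))
  out
}
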