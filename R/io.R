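#' Read an instrument-style CSV with `#key=value` metadata header
#'
#' The single tabular dialect used throughout: plain CSV preceded by
#' optional comment lines `#key=value` carrying experiment metadata.
#' Columns are matched by header name, so column order is irrelevant.
#'
#' @param path file path
#' @param required character vector of required column names
#' @return list with `data` (data.frame, numeric columns parsed) and `meta`
#'   (named character)
#' @keywords internal
read_csv_meta <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (m in sub("^#", "", lines[is_meta])) {
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  # locate malformed numeric cells with their file line numbers
  header_line <- which(!is_meta & nzchar(trimws(lines)))[1]
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error in %s: non-numeric '%s' in column '%s' at line %d",
                     path, v[bad[1]], col, header_line + bad[1]))
      df[[col]] <- num
    }
  }
  list(data = df, meta = meta)
}

write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a typed experiment table
#'
#' Dispatches on `schema` to the module-specific reader and returns the
#' module's container type. Temperatures in files are Celsius (instrument
#' convention) and are converted to kelvin on read.
#'
#' @param path CSV file path
#' @param schema one of `"melt"`, `"itc"`, `"decay"`, `"frap"`,
#'   `"peptide"`, `"densitometry"`
#' @return a `melt_curve`, `itc_experiment`, `decay_series`, `frap_trace`,
#'   `peptide_table` or densitometry data.frame
#' @export
read_experiment_table <- function(path,
                                  schema = c("melt", "itc", "decay", "frap",
                                             "peptide", "densitometry")) {
  schema <- match.arg(schema)
  switch(schema,
    melt = {
      x <- read_csv_meta(path, c("temperature_C", "signal"))
      melt_curve(celsius_to_kelvin(x$data$temperature_C), x$data$signal,
                 condition = x$meta$condition %||% NA_character_)
    },
    itc = {
      x <- read_csv_meta(path, c("injection_index", "volume_uL", "heat_ucal"))
      m <- x$meta
      need <- c("cell_volume_uL", "cell_conc_uM", "syringe_conc_uM",
                "temperature_C")
      if (!all(need %in% names(m)))
        stop("schema error: itc metadata must carry ",
             paste(need, collapse = ", "))
      d <- itc_design(
        cell_volume_uL = as.numeric(m$cell_volume_uL),
        n_injections = nrow(x$data),
        injection_volume_uL = x$data$volume_uL[order(x$data$injection_index)],
        cell_conc_uM = as.numeric(m$cell_conc_uM),
        syringe_conc_uM = as.numeric(m$syringe_conc_uM),
        temperature_K = celsius_to_kelvin(as.numeric(m$temperature_C)),
        buffer_dH_ion = as.numeric(m$buffer_dH_ion_kcal_mol %||% 0),
        buffer = m$buffer %||% NA_character_)
      itc_experiment(d, x$data$heat_ucal[order(x$data$injection_index)],
                     condition = m$condition %||% NA_character_)
    },
    decay = {
      x <- read_csv_meta(path, c("time_h", "value"))
      decay_series(x$data$time_h, x$data$value,
                   condition = x$meta$condition %||% NA_character_)
    },
    frap = {
      x <- read_csv_meta(path, c("time_s", "intensity"))
      if (!"phase" %in% names(x$data))
        stop("schema error: frap table needs a 'phase' column (pre/post)")
      t <- x$data$time_s
      # encode phase in the sign convention frap_trace expects
      t[x$data$phase == "pre" & t >= 0] <- -abs(t[x$data$phase == "pre" & t >= 0]) - 1e-9
      frap_trace(t, x$data$intensity,
                 condition = x$meta$condition %||% NA_character_)
    },
    peptide = {
      x <- read_csv_meta(path, "peptides")
      need <- c("protein", "sample", "role", "peptides")
      missing <- setdiff(need, names(x$data))
      if (length(missing))
        stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
      d <- x$data
      samples <- unique(d$sample)
      proteins <- unique(d$protein)
      counts <- matrix(0L, length(proteins), length(samples),
                       dimnames = list(proteins, samples))
      counts[cbind(match(d$protein, proteins), match(d$sample, samples))] <-
        as.integer(d$peptides)
      roles <- d$role[match(samples, d$sample)]
      peptide_table(counts, roles)
    },
    densitometry = {
      x <- read_csv_meta(path, c("target", "loading1"))
      need <- c("group", "replicate")
      missing <- setdiff(need, names(x$data))
      if (length(missing))
        stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
      x$data
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated dataset in its module's CSV dialect
#'
#' Emits exactly the files [read_experiment_table()] parses, so
#' write-then-read round-trips values to float precision.
#'
#' @param x a `melt_curve`, `itc_experiment`, `decay_series` or `frap_trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_experiment_table <- function(x, path) {
  if (inherits(x, "melt_curve")) {
    write_csv_meta(data.frame(temperature_C = kelvin_to_celsius(x$temperature_K),
                              signal = x$signal),
                   path, meta = drop_na_meta(condition = attr(x, "condition")))
  } else if (inherits(x, "itc_experiment")) {
    d <- x$design
    write_csv_meta(
      data.frame(injection_index = seq_along(x$heats_ucal),
                 volume_uL = d$injection_volume_uL,
                 heat_ucal = x$heats_ucal),
      path,
      meta = drop_na_meta(cell_volume_uL = d$cell_volume_uL,
                          cell_conc_uM = d$cell_conc_uM,
                          syringe_conc_uM = d$syringe_conc_uM,
                          temperature_C = kelvin_to_celsius(d$temperature_K),
                          buffer = d$buffer,
                          buffer_dH_ion_kcal_mol = d$buffer_dH_ion,
                          condition = x$condition))
  } else if (inherits(x, "decay_series")) {
    write_csv_meta(data.frame(time_h = x$time_h, value = x$value),
                   path, meta = drop_na_meta(condition = attr(x, "condition")))
  } else if (inherits(x, "frap_trace")) {
    write_csv_meta(data.frame(time_s = x$time_s, intensity = x$intensity,
                              phase = x$phase),
                   path, meta = drop_na_meta(condition = attr(x, "condition")))
  } else stop("unsupported object of class ", class(x)[1])
  invisible(path)
}

drop_na_meta <- function(...) {
  m <- list(...)
  m[!vapply(m, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]
}

#' Serialize a stage result with full provenance
#'
#' Every result JSON embeds the stage name, parameters, seed, input file
#' checksum (when an input path is given) and the package version, so a
#' result file alone suffices to re-run its stage.
#'
#' @param result named list of stage outputs (numbers/strings/vectors)
#' @param path output JSON path
#' @param stage stage name
#' @param params named list of stage parameters
#' @param seed integer seed used (NA for deterministic stages)
#' @param input optional input file path (checksummed)
#' @return `path`, invisibly
#' @export
write_result_json <- function(result, path, stage, params = list(),
                              seed = NA_integer_, input = NULL) {
  bundle <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("isophys")),
    seed = seed,
    params = params,
    input_md5 = if (!is.null(input)) unname(tools::md5sum(input)) else NA_character_,
    result = result)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Run a named analysis stage on a file
#'
#' Thin dispatcher tying the readers to the fitters; used by the analysis
#' scripts. Unknown stages are an error.
#'
#' @param stage one of `"fit-melt"`, `"fit-itc"`, `"fit-decay"`,
#'   `"fit-frap"`, `"filter-interactors"`
#' @param input input CSV path
#' @param output optional result JSON path
#' @param params named list of stage parameters (e.g. `discard_first`,
#'   `min_peptides`)
#' @return the stage's native result object, invisibly when `output` given
#' @export
run_stage <- function(stage, input, output = NULL, params = list()) {
  res <- switch(stage,
    "fit-melt" = {
      fit <- fit_two_state(read_experiment_table(input, "melt"),
                           fix_dCp = params$fix_dCp %||% TRUE)
      list(obj = fit,
           json = list(T_m_K = fit$params$T_m, T_m_C = kelvin_to_celsius(fit$params$T_m),
                       dH_m_kcal_mol = fit$params$dH_m,
                       dCp_unf = fit$params$dCp_unf,
                       residual_sd = fit$residual_sd, converged = fit$converged))
    },
    "fit-itc" = {
      fit <- fit_single_site(read_experiment_table(input, "itc"),
                             discard_first = params$discard_first %||% TRUE)
      list(obj = fit,
           json = list(n = fit$n, K_d_M = fit$K_d, K_d_uM = fit$K_d * 1e6,
                       dG_kcal_mol = fit$dG, dH_kcal_mol = fit$dH,
                       mTdS_kcal_mol = fit$mTdS,
                       q_dil_kcal_mol = fit$q_dil,
                       c_value = attr(fit, "c_value"),
                       converged = attr(fit, "converged"),
                       warnings = attr(fit, "warnings")))
    },
    "fit-decay" = {
      fit <- fit_decay(read_experiment_table(input, "decay"),
                       pin_A = params$pin_A %||% FALSE)
      list(obj = fit, json = list(k_per_h = fit$k, t_half_h = fit$t_half,
                                  amplitude = fit$amplitude,
                                  boundary = fit$boundary))
    },
    "fit-frap" = {
      fit <- fit_frap(read_experiment_table(input, "frap"))
      list(obj = fit, json = list(k_per_s = fit$k, t_half_s = fit$t_half,
                                  mobile_fraction = fit$mobile_fraction,
                                  floor = fit$floor, plateau = fit$plateau))
    },
    "filter-interactors" = {
      hits <- filter_interactors(read_experiment_table(input, "peptide"),
                                 min_peptides = params$min_peptides %||% 2)
      list(obj = hits, json = list(interactors = as.character(hits),
                                   evidence = attr(hits, "evidence")))
    },
    stop("unknown stage: ", stage))
  if (!is.null(output)) {
    write_result_json(res$json, output, stage = stage, params = params,
                      seed = params$seed %||% NA_integer_, input = input)
    return(invisible(res$obj))
  }
  res$obj
}
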