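#' Table schemas used by the pipeline
#'
#' Named column specifications for each interchange CSV.  `required` names
#' must be present (case- and order-insensitive); `numeric` names are
#' coerced and validated row by row.
#'
#' @format list of schema definitions.
#' @export
osmoscale_schemas <- list(
  shifts = list(
    required = c("cell_id", "compartment", "c_iso", "c_out",
                 "v_iso_um3", "v_um3"),
    optional = c("group", "conc_units", "v_before_um3", "delta_c"),
    numeric = c("c_iso", "c_out", "v_iso_um3", "v_um3")),
  tracks = list(
    required = c("track_id", "frame", "x_um", "y_um"),
    optional = c("t_s", "compartment", "condition"),
    numeric = c("frame", "x_um", "y_um")),
  trajectories = list(
    required = c("cell_id", "t_min", "vc_um3", "vn_um3"),
    optional = c("nc", "mitotic"),
    numeric = c("t_min", "vc_um3", "vn_um3")),
  deff_conc = list(
    required = c("conc", "deff"),
    optional = character(),
    numeric = c("conc", "deff"))
)

#' Read and validate an interchange CSV
#'
#' Headers are matched case-insensitively and in any order; unknown extra
#' columns are kept with a warning; missing required columns or unparsable
#' numeric cells raise errors naming the offending columns/rows.
#'
#' @param path CSV file path.
#' @param schema schema name (one of `names(osmoscale_schemas)`) or a
#'   schema list.
#' @return validated data.frame with lower-case canonical column names.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema)) {
    if (!schema %in% names(osmoscale_schemas))
      stop("unknown schema '", schema, "'", call. = FALSE)
    schema <- osmoscale_schemas[[schema]]
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(schema$required, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), c(schema$required, schema$optional))
  if (length(extra))
    warning("ignoring schema: extra column(s) kept: ",
            paste(extra, collapse = ", "), call. = FALSE)
  bad <- character()
  for (col in schema$numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    new_na <- is.na(v) & !is.na(df[[col]])
    if (any(new_na))
      bad <- c(bad, sprintf("%s (rows %s)", col,
                            paste(utils::head(which(new_na), 5), collapse = ",")))
    df[[col]] <- v
  }
  if (length(bad))
    stop("unparsable numeric cells in: ", paste(bad, collapse = "; "),
         call. = FALSE)
  df
}

#' Write an interchange CSV
#'
#' Plain-text CSV writer used by all pipeline stages (no row names,
#' full precision).
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic per-stage seed fan-out from the top-level seed
.stage_seed <- function(seed, stage_index) {
  (seed * 1009L + stage_index * 9176L) %% .Machine$integer.max
}

#' Run a multi-stage analysis pipeline
#'
#' Executes named stages in order, passing files through an output
#' directory, and writes a JSON manifest recording the configuration,
#' per-stage seeds, input/output file MD5 hashes and summary numbers.
#' Supported stages: `synth_shifts` (generator parameters as the stage
#' params), `bvh_fit` (input: shifts CSV), `synth_tracks`
#' (`motion = "brownian"` or `"fbm"`), `gem_fit` (input: tracks CSV;
#' reports D_eff and alpha), `synth_population`, `homeostasis_fit`.
#'
#' @param config list with elements `seed` (integer), `out_dir`, and
#'   `stages`: a named list, one element per stage, each a list of that
#'   stage's parameters (may be empty for defaults).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("osmoscale_run_")
             else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  known <- c("synth_shifts", "bvh_fit", "synth_tracks", "gem_fit",
             "synth_population", "homeostasis_fit")
  unknown <- setdiff(names(stages), known)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  manifest <- list(seed = seed, out_dir = out_dir, stages = list())
  files <- list()
  for (i in seq_along(stages)) {
    name <- names(stages)[i]
    pars <- stages[[i]]
    st_seed <- .stage_seed(seed, i)
    entry <- tryCatch(
      .run_stage(name, pars, st_seed, out_dir, files),
      error = function(e) {
        manifest$failed_stage <- name
        manifest$error <- conditionMessage(e)
        .write_manifest(manifest, out_dir)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    files <- entry$files
    manifest$stages[[name]] <- entry$summary
  }
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

.run_stage <- function(name, pars, st_seed, out_dir, files) {
  md5 <- function(p) unname(tools::md5sum(p))
  if (name == "synth_shifts") {
    args <- c(list(seed = st_seed), pars)
    df <- do.call(gen_shift_dataset, args)
    p <- file.path(out_dir, "shifts.csv")
    write_table(df, p)
    files$shifts <- p
    return(list(files = files,
                summary = list(seed = st_seed, n = nrow(df), file = p,
                               md5 = md5(p))))
  }
  if (name == "bvh_fit") {
    src <- if (!is.null(pars$input)) pars$input else files$shifts
    if (is.null(src)) stop("no shifts table available", call. = FALSE)
    df <- read_table(src, "shifts")
    fit <- fit_bvh_linear(normalize_shift_data(df))
    p <- file.path(out_dir, "bvh_fit.csv")
    write_table(data.frame(slope = fit$slope, intercept = fit$intercept,
                           se_slope = fit$stderr_slope,
                           se_intercept = fit$stderr_intercept,
                           r2 = fit$r_squared, lof_p = fit$lack_of_fit_p,
                           n = fit$n_points), p)
    return(list(files = files,
                summary = list(input_md5 = md5(src), file = p,
                               slope = fit$slope, intercept = fit$intercept)))
  }
  if (name == "synth_tracks") {
    motion <- if (is.null(pars$motion)) "brownian" else pars$motion
    pars$motion <- NULL
    df <- if (motion == "fbm")
      do.call(gen_fbm_tracks, c(list(seed = st_seed), pars))
    else
      do.call(gen_brownian_tracks, c(list(seed = st_seed), pars))
    p <- file.path(out_dir, "tracks.csv")
    write_table(df, p)
    files$tracks <- p
    return(list(files = files,
                summary = list(seed = st_seed, motion = motion,
                               n_tracks = length(unique(df$track_id)),
                               file = p, md5 = md5(p))))
  }
  if (name == "gem_fit") {
    src <- if (!is.null(pars$input)) pars$input else files$tracks
    if (is.null(src)) stop("no tracks table available", call. = FALSE)
    df <- read_table(src, "tracks")
    dt <- if (is.null(pars$dt)) 0.01 else pars$dt
    msd <- compute_msd(df, dt = dt)
    dfit <- fit_deff(msd)
    afit <- fit_alpha(msd)
    p <- file.path(out_dir, "gem_fit.csv")
    write_table(data.frame(deff = dfit$D_eff, se_deff = dfit$stderr_D,
                           alpha = afit$alpha, se_alpha = afit$stderr_alpha,
                           n_tracks = msd$n_tracks), p)
    return(list(files = files,
                summary = list(input_md5 = md5(src), file = p,
                               deff = dfit$D_eff, alpha = afit$alpha)))
  }
  if (name == "synth_population") {
    df <- do.call(gen_homeostasis_population, c(list(seed = st_seed), pars))
    p <- file.path(out_dir, "trajectories.csv")
    write_table(df, p)
    files$trajectories <- p
    return(list(files = files,
                summary = list(seed = st_seed,
                               n_cells = length(unique(df$cell_id)),
                               file = p, md5 = md5(p))))
  }
  if (name == "homeostasis_fit") {
    src <- if (!is.null(pars$input)) pars$input else files$trajectories
    if (is.null(src)) stop("no trajectory table available", call. = FALSE)
    df <- read_table(src, "trajectories")
    gfit <- fit_growth_rate(df)
    hfit <- fit_correction_rate(df)
    p <- file.path(out_dir, "homeostasis_fit.csv")
    write_table(data.frame(gammaC = gfit$gammaC, se_gammaC = gfit$stderr,
                           gammaNC = hfit$gammaNC,
                           se_gammaNC = hfit$stderr_gammaNC,
                           f0_hat = hfit$f0_hat, se_f0 = hfit$stderr_f0,
                           n_cells = hfit$n_cells), p)
    return(list(files = files,
                summary = list(input_md5 = md5(src), file = p,
                               gammaC = gfit$gammaC, gammaNC = hfit$gammaNC,
                               f0_hat = hfit$f0_hat)))
  }
  stop("unhandled stage '", name, "'", call. = FALSE)
}
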