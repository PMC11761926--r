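#' Write a trial set to long-form CSV
#'
#' Canonical on-disk format: one row per sample with columns `participant`,
#' `condition`, `trial`, `muscle`, `sample_index` (0-based), `value`. A JSON
#' sidecar (same path with extension `.json`) records the sampling rate and,
#' for simulated data, the design, effect map, seed and theoretical band
#' coherence per planted cell.
#'
#' @param trials An `emg_trial_set`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_trials_csv <- function(trials, path, sidecar = TRUE) {
  stopifnot(inherits(trials, "emg_trial_set"))
  n <- nrow(trials$samples)
  m <- ncol(trials$samples)
  dt <- data.table::data.table(
    participant = rep(trials$meta$participant, each = n),
    condition = rep(trials$meta$condition, each = n),
    trial = rep(trials$meta$trial, each = n),
    muscle = rep(trials$meta$muscle, each = n),
    sample_index = rep.int(0:(n - 1), m),
    value = as.vector(trials$samples)
  )
  data.table::fwrite(dt, path)
  if (sidecar) {
    side <- list(fs = trials$fs, n_samples = n, seed = trials$seed)
    if (!is.null(trials$design)) {
      side$design <- unclass(trials$design)
    }
    if (!is.null(trials$effects) && nrow(trials$effects) > 0) {
      side$effects <- as.data.frame(trials$effects)
    }
    if (!is.null(trials$theory)) side$theory <- trials$theory
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", ".json", path)
}

#' Read trials from long-form CSV
#'
#' Reads the canonical long CSV (columns `participant`, `condition`,
#' `trial`, `muscle`, `sample_index`, `value`), validates the layout, and
#' returns an `emg_trial_set`. The sampling rate is taken from the JSON
#' sidecar when present, else from `fs`. Recordings whose length differs
#' from the modal length are excluded with a warning (they cannot enter the
#' fixed-grid coherence analysis); recordings are ordered by (participant,
#' condition, trial, muscle).
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz; overridden by the sidecar if one exists.
#' @return An `emg_trial_set` with an `excluded` attribute listing dropped
#'   recordings, if any.
#' @export
read_trials <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  required <- c("participant", "condition", "trial", "muscle",
                "sample_index", "value")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sp <- sidecar_path(path)
  side <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
          else NULL
  if (!is.null(side$fs)) fs <- side$fs
  if (is.null(fs)) stop("sampling rate unknown: no sidecar and no fs argument")

  data.table::setorderv(dt, c("participant", "condition", "trial", "muscle",
                              "sample_index"))
  key <- paste(dt$participant, dt$condition, dt$trial, dt$muscle, sep = "\r")
  lens <- table(factor(key, levels = unique(key)))
  n_modal <- as.integer(names(sort(table(as.integer(lens)),
                                   decreasing = TRUE))[1])
  bad <- names(lens)[as.integer(lens) != n_modal]
  if (length(bad) > 0) {
    warning(sprintf(
      "%d recording(s) excluded: sample count differs from the modal %d",
      length(bad), n_modal))
    keep <- !(key %in% bad)
    dt <- dt[keep, , drop = FALSE]
    key <- key[keep]
  }
  ukey <- unique(key)
  m <- length(ukey)
  samples <- matrix(dt$value, nrow = n_modal, ncol = m)
  first <- match(ukey, key)
  meta <- data.frame(participant = as.character(dt$participant[first]),
                     condition = as.character(dt$condition[first]),
                     trial = as.integer(dt$trial[first]),
                     muscle = as.character(dt$muscle[first]),
                     stringsAsFactors = FALSE)
  out <- structure(
    list(samples = samples, meta = meta, fs = fs, design = NULL,
         effects = NULL, seed = side$seed, theory = side$theory),
    class = "emg_trial_set"
  )
  if (length(bad) > 0) {
    attr(out, "excluded") <- gsub("\r", "/", bad, fixed = TRUE)
  }
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits the tidy coherence and Dunnett tables as TSV, the run summary and
#' configuration echo as JSON, and a manifest listing every file with its
#' MD5 checksum. Output is byte-stable for identical inputs.
#'
#' @param run An `imcoh_run` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "imcoh_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- c(coherence = "coherence.tsv", dunnett = "dunnett.tsv",
             summary = "summary.json", config = "config.json")
  data.table::fwrite(run$coherence, file.path(out_dir, files["coherence"]),
                     sep = "\t")
  data.table::fwrite(run$dunnett, file.path(out_dir, files["dunnett"]),
                     sep = "\t")
  jsonlite::write_json(run$summary, file.path(out_dir, files["summary"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- run$config
  cfg_json <- list(
    welch = cfg$welch[c("window_duration", "overlap", "fs", "detrend")],
    bands = cfg$bands, analyzed_bands = cfg$analyzed_bands,
    pairs = cfg$pairs, baseline = cfg$baseline, alpha = cfg$alpha,
    notch = if (!is.null(cfg$notch))
      cfg$notch[c("kind", "center", "bandwidth", "order", "fs")],
    rectify = cfg$rectify, zero_phase = cfg$zero_phase
  )
  jsonlite::write_json(cfg_json, file.path(out_dir, files["config"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- file.path(out_dir, files)
  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
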