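#' Muscle pairs analyzed
#'
#' The nine left-unilateral, right-unilateral and bilateral-homologous pairs
#' of the lower-leg muscle set. By default the two bilateral plantarflexor
#' homologous pairs (`LMG:RMG`, `LS:RS`) are excluded from analysis, the
#' conventional reduction when those pairs show insufficient EMG
#' connectivity; pass `include_bilateral_homologous = TRUE` to keep all
#' nine.
#'
#' @param include_bilateral_homologous Keep `LMG:RMG` and `LS:RS`.
#' @return Character vector of `"A:B"` pair labels.
#' @export
default_pairs <- function(include_bilateral_homologous = FALSE) {
  pairs <- c("LTA:LMG", "LTA:LS", "LMG:LS",
             "RTA:RMG", "RTA:RS", "RMG:RS",
             "LTA:RTA", "LMG:RMG", "LS:RS")
  if (include_bilateral_homologous) pairs
  else setdiff(pairs, c("LMG:RMG", "LS:RS"))
}

#' Analysis run configuration
#'
#' Bundles every tunable of the coherence pipeline: Welch parameters, band
#' definitions and the subset actually analyzed, muscle pairs, baseline
#' condition, familywise alpha, and filter options. Condition order in all
#' outputs follows the input data's design order, not alphabetical order.
#'
#' @param welch A [welch_params()] object.
#' @param bands Band definition data.frame (see [band_definitions()]).
#' @param analyzed_bands Names of bands to analyze; defaults to alpha, beta,
#'   lower gamma and upper gamma (delta and theta are masked by the 10 Hz
#'   acquisition high-pass and re-enabling them triggers a warning).
#' @param pairs Muscle pairs (`"A:B"`).
#' @param include_bilateral_homologous Passed to [default_pairs()] when
#'   `pairs` is `NULL`.
#' @param baseline Baseline condition label.
#' @param alpha Familywise significance level for the Dunnett comparisons.
#' @param notch A `filter_spec` for powerline removal, or `NULL` to skip.
#' @param rectify Full-wave rectify (absolute value about the mean) before
#'   coherence estimation; off by default.
#' @param zero_phase Use forward-backward filtering.
#' @param run_assumptions Attach Shapiro/Levene/ANOVA screens per analysis
#'   set.
#' @return An object of class `run_config`.
#' @export
run_config <- function(welch = welch_params(),
                       bands = band_definitions(),
                       analyzed_bands = default_analyzed_bands(),
                       pairs = NULL,
                       include_bilateral_homologous = FALSE,
                       baseline = "EOFT",
                       alpha = 0.05,
                       notch = design_notch(fs = welch$fs),
                       rectify = FALSE,
                       zero_phase = FALSE,
                       run_assumptions = FALSE) {
  if (is.null(pairs)) {
    pairs <- default_pairs(include_bilateral_homologous)
  }
  split_pair(pairs)  # validates syntax
  stopifnot(all(analyzed_bands %in% bands$band), alpha > 0, alpha < 1)
  if (any(analyzed_bands %in% c("delta", "theta"))) {
    warning("delta/theta bands are analyzed although a 10 Hz acquisition ",
            "high-pass typically masks coherence there; interpret with care")
  }
  structure(
    list(welch = welch, bands = bands, analyzed_bands = analyzed_bands,
         pairs = pairs, baseline = baseline, alpha = alpha, notch = notch,
         rectify = rectify, zero_phase = zero_phase,
         run_assumptions = run_assumptions),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("imcoh run configuration\n")
  cat(sprintf("  baseline %s, alpha %g, %d pairs, bands: %s\n",
              x$baseline, x$alpha, length(x$pairs),
              paste(x$analyzed_bands, collapse = ", ")))
  print(x$welch)
  invisible(x)
}

# internal: MSC spectrum from precomputed segment FFT matrices
msc_from_ffts <- function(X, Y, params) {
  sc <- onesided_scale(params$window_samples, params$fs)
  m <- sc$scale * sc$mult
  Pxx <- rowMeans(abs(X)^2) * m
  Pyy <- rowMeans(abs(Y)^2) * m
  Pxy <- rowMeans(Conj(X) * Y) * m
  denom <- Pxx * Pyy
  msc <- rep(NA_real_, length(denom))
  ok <- denom > 0
  msc[ok] <- Mod(Pxy[ok])^2 / denom[ok]
  structure(
    list(freq = welch_grid(params$window_samples, params$fs), msc = msc,
         L = ncol(X), Pxx = Pxx, Pyy = Pyy, Pxy = Pxy, params = params),
    class = "coherence_spectrum"
  )
}

#' Band coherence table for every trial and muscle pair
#'
#' Preprocesses each recording (notch filter, optional rectification) and
#' computes the band-averaged magnitude-squared coherence for every
#' (participant, condition, trial, muscle pair, analyzed band) cell. Both
#' channels of a pair are always segmented and filtered identically.
#'
#' @param trials An `emg_trial_set` (simulated or read from disk).
#' @param config A [run_config()].
#' @return Tidy data.frame: `participant`, `condition`, `trial`, `pair`,
#'   `band`, `value`, `n_bins`, `n_undefined`, `L`.
#' @export
coherence_table <- function(trials, config = run_config()) {
  stopifnot(inherits(trials, "emg_trial_set"), inherits(config, "run_config"))
  if (abs(config$welch$fs - trials$fs) > 1e-9) {
    stop(sprintf("Welch parameters assume fs = %g Hz but trials have fs = %g Hz",
                 config$welch$fs, trials$fs))
  }
  pair_mus <- split_pair(config$pairs)
  mus_needed <- unique(unlist(pair_mus))
  missing_mus <- setdiff(mus_needed, unique(trials$meta$muscle))
  if (length(missing_mus) > 0) {
    stop("configured pairs reference muscle(s) absent from the data: ",
         paste(missing_mus, collapse = ", "))
  }
  bands <- config$bands[config$bands$band %in% config$analyzed_bands, ,
                        drop = FALSE]
  bands <- bands[match(config$analyzed_bands, bands$band), , drop = FALSE]

  meta <- trials$meta
  key <- interaction(meta$participant, meta$condition, meta$trial,
                     drop = TRUE, lex.order = TRUE)
  grp_cols <- split(seq_len(nrow(meta)), key)
  rows <- vector("list", length(grp_cols))
  ri <- 0L
  for (g in grp_cols) {
    gm <- meta[g, , drop = FALSE]
    ffts <- new.env(parent = emptyenv())
    get_fft <- function(mu) {
      if (!is.null(ffts[[mu]])) return(ffts[[mu]])
      i <- g[match(mu, gm$muscle)]
      x <- trials$samples[, i]
      if (!is.null(config$notch)) {
        x <- apply_filter(x, config$notch, zero_phase = config$zero_phase)
      }
      if (config$rectify) x <- abs(x - mean(x))
      ffts[[mu]] <- segment_ffts(x, config$welch)
      ffts[[mu]]
    }
    recs <- vector("list", length(config$pairs))
    for (pi in seq_along(config$pairs)) {
      mu <- pair_mus[[pi]]
      spec <- msc_from_ffts(get_fft(mu[1]), get_fft(mu[2]), config$welch)
      vals <- lapply(seq_len(nrow(bands)), function(bi) {
        ba <- band_average(spec, bands$lo[bi], bands$hi[bi])
        data.frame(participant = gm$participant[1],
                   condition = gm$condition[1], trial = gm$trial[1],
                   pair = config$pairs[pi], band = bands$band[bi],
                   value = ba$value, n_bins = ba$n_bins,
                   n_undefined = ba$n_undefined, L = spec$L,
                   stringsAsFactors = FALSE)
      })
      recs[[pi]] <- do.call(rbind, vals)
    }
    ri <- ri + 1L
    rows[[ri]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dunnett tables from a coherence table
#'
#' Splits the coherence table into analysis sets (participant x pair x
#' band), runs [dunnett_many_to_one()] against the baseline within each,
#' and returns one tidy table of all comparisons.
#'
#' @param coh Coherence table from [coherence_table()].
#' @param config A [run_config()].
#' @param condition_order Condition ordering for the output (defaults to
#'   first appearance in `coh`).
#' @return Tidy data.frame: `participant`, `pair`, `band`, `condition`,
#'   `n`, `diff`, `se`, `t`, `ci_lo`, `ci_hi`, `p_adj`, `significant`,
#'   `df`, `crit`, `alpha`, `degenerate`, plus (if requested) an
#'   `assumptions` attribute keyed by analysis set.
#' @export
dunnett_table <- function(coh, config = run_config(),
                          condition_order = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(condition_order)) condition_order <- unique(coh$condition)
  if (!config$baseline %in% condition_order) {
    stop(sprintf("baseline condition '%s' absent from the coherence table",
                 config$baseline))
  }
  key <- interaction(coh$participant, coh$pair, coh$band, drop = TRUE,
                     lex.order = TRUE)
  sets <- split(seq_len(nrow(coh)), key)
  out <- vector("list", length(sets))
  screens <- if (config$run_assumptions) vector("list", length(sets)) else NULL
  set_names <- character(length(sets))
  for (i in seq_along(sets)) {
    rows <- coh[sets[[i]], , drop = FALSE]
    dn <- dunnett_many_to_one(rows$value, rows$condition,
                              baseline = config$baseline,
                              alpha = config$alpha,
                              condition_order = condition_order)
    dn <- cbind(participant = rows$participant[1], pair = rows$pair[1],
                band = rows$band[1], dn, stringsAsFactors = FALSE)
    out[[i]] <- dn
    set_names[i] <- paste(rows$participant[1], rows$pair[1], rows$band[1],
                          sep = "|")
    if (config$run_assumptions) {
      screens[[i]] <- assumption_screen(rows$value, rows$condition)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # stable ordering: participant, pair, band, then configured condition order
  res <- res[order(res$participant, res$pair, res$band,
                   match(res$condition, condition_order)), , drop = FALSE]
  rownames(res) <- NULL
  if (config$run_assumptions) {
    names(screens) <- set_names
    attr(res, "assumptions") <- screens
  }
  res
}

#' Run the full coherence pipeline
#'
#' Preprocess -> Welch MSC -> band averaging -> per-participant Dunnett
#' many-to-one inference, with bookkeeping. Fully deterministic given the
#' input trials and configuration.
#'
#' @param trials An `emg_trial_set`.
#' @param config A [run_config()].
#' @return An object of class `imcoh_run`: list with `coherence` (band
#'   coherence table), `dunnett` (comparison table) and `summary` (counts:
#'   trials read, analysis sets, values per set, comparisons per set;
#'   configuration echo).
#' @export
run_pipeline <- function(trials, config = run_config()) {
  stopifnot(inherits(trials, "emg_trial_set"))
  cond_order <- unique(trials$meta$condition)
  coh <- coherence_table(trials, config)
  dn <- dunnett_table(coh, config, condition_order = cond_order)
  n_sets <- length(unique(paste(coh$participant, coh$pair, coh$band)))
  per_set <- nrow(coh) / n_sets
  summary <- list(
    n_recordings = ncol(trials$samples),
    n_trials = nrow(unique(trials$meta[, c("participant", "condition",
                                           "trial")])),
    n_participants = length(unique(trials$meta$participant)),
    n_conditions = length(cond_order),
    condition_order = cond_order,
    n_pairs = length(config$pairs),
    analyzed_bands = config$analyzed_bands,
    n_analysis_sets = n_sets,
    values_per_set = per_set,
    comparisons_per_set = length(cond_order) - 1L,
    all_pairs_comparisons = comparison_counts(length(cond_order))$all_pairs,
    coherence_rows = nrow(coh),
    dunnett_rows = nrow(dn),
    baseline = config$baseline,
    alpha = config$alpha
  )
  structure(list(coherence = coh, dunnett = dn, summary = summary,
                 config = config),
            class = "imcoh_run")
}

#' @export
print.imcoh_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "imcoh run: %d analysis sets of %g values (%d participants x %d pairs x %d bands)\n",
    s$n_analysis_sets, s$values_per_set, s$n_participants, s$n_pairs,
    length(s$analyzed_bands)))
  cat(sprintf("  %d Dunnett comparisons (%d per set) vs baseline %s, alpha %g\n",
              s$dunnett_rows, s$comparisons_per_set, s$baseline, s$alpha))
  cat(sprintf("  significant: %d of %d\n",
              sum(x$dunnett$significant, na.rm = TRUE), nrow(x$dunnett)))
  invisible(x)
}
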