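#' Observed time-course dataset
#'
#' Container for an NMR-derived time course of species mole fractions
#' together with the pH log and the initial state needed to simulate the
#' experiment.
#'
#' @param model_kind `"trisaccharide"` or `"ggm"`.
#' @param sample_times Non-decreasing sampling times (hours).
#' @param observations Matrix or data frame (time x species) of mole
#'   fractions in \[0, 1\]; `NA` marks a missing observation (excluded
#'   from any fit). Column names must come from [species_names()];
#'   species without a column are treated as unobserved.
#' @param ph_profile A [ph_profile()]; default constant pH 8.
#' @param initial_state Full state vector at time 0. If `NULL` and the
#'   first sample is at time 0 with a complete row, that row is used.
#' @param label Free-text label (e.g. `"from 1a"`, `"GGM 2 mg/ml"`).
#' @param row_sum_tol Allowed excess of a row sum over 1 (noise head
#'   room), default 0.05.
#' @param value_tol Allowed excursion of individual observations outside
#'   \[0, 1\] (default essentially none); unclipped noisy data may use a
#'   few noise standard deviations.
#' @return An object of class `timecourse_dataset`.
#' @export
timecourse_dataset <- function(model_kind, sample_times, observations,
                               ph_profile = NULL, initial_state = NULL,
                               label = "", row_sum_tol = 0.05,
                               value_tol = 1e-9) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  sp <- species_names(model_kind)
  sample_times <- check_times(sample_times)
  obs <- as.matrix(observations)
  if (is.null(colnames(obs))) {
    stop("observations must have species column names", call. = FALSE)
  }
  unknown <- setdiff(colnames(obs), sp)
  if (length(unknown)) {
    stop("unknown species column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(obs) != length(sample_times)) {
    stop("observations must have one row per sample time", call. = FALSE)
  }
  storage.mode(obs) <- "double"
  if (any(obs < -value_tol | obs > 1 + value_tol, na.rm = TRUE)) {
    stop("observations must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(obs, na.rm = TRUE)
  bad <- which(sums > 1 + row_sum_tol)
  if (length(bad)) {
    stop("row sum exceeds 1 + tolerance at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  profile <- as_ph_profile(ph_profile)
  if (is.null(initial_state)) {
    if (sample_times[1] == 0 && !anyNA(obs[1, ]) &&
        length(colnames(obs)) == length(sp)) {
      initial_state <- obs[1, sp]
    } else {
      stop("initial_state is required unless the first row is a complete ",
           "observation at time 0", call. = FALSE)
    }
  }
  initial_state <- as_state(initial_state, model_kind)
  structure(list(model_kind = model_kind,
                 sample_times = sample_times,
                 observations = obs,
                 observed_species = colnames(obs),
                 ph_profile = profile,
                 initial_state = initial_state,
                 label = label),
            class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat(sprintf("Time-course dataset (%s%s): %d samples over %.3g h, species: %s\n",
              x$model_kind,
              if (nzchar(x$label)) paste0(", ", x$label) else "",
              length(x$sample_times), max(x$sample_times),
              paste(x$observed_species, collapse = ", ")))
  invisible(x)
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "timecourse_dataset")) return(list(datasets))
  if (!is.list(datasets) || !length(datasets) ||
      !all(vapply(datasets, inherits, logical(1), "timecourse_dataset"))) {
    stop("datasets must be a timecourse_dataset or a list of them",
         call. = FALSE)
  }
  datasets
}
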