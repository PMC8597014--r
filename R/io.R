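# CSV interchange: comma-separated, "." decimal, UTF-8, "#" metadata
# comment lines of the form "# key: value". Times are hours throughout;
# a "time_unit: d" metadata key converts days to hours on load.

format_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

read_metadata_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Read a time-course CSV file
#'
#' Expects a header `time_h` plus species columns drawn from the fixed
#' orderings (`c_1a` ... `c_1g` or `c_A` ... `c_D`), optionally preceded
#' by `# key: value` metadata lines (`model_kind`, `label`,
#' `initial_state` as comma-separated fractions, `time_unit` in
#' `{h, d}`). Empty cells are missing observations.
#'
#' @param path Path to the CSV file.
#' @param ph_profile Optional [ph_profile()] to attach (e.g. from
#'   [read_ph_log()]); default constant pH 8.
#' @return A [timecourse_dataset()].
#' @export
read_timecourse_csv <- function(path, ph_profile = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- read_metadata_lines(lines)
  df <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                              collapse = "\n"),
                 check.names = FALSE)
  if (!"time_h" %in% names(df)) {
    stop("time-course CSV must have a 'time_h' column", call. = FALSE)
  }
  times <- df$time_h
  if (is.unsorted(times)) {
    stop("non-monotone times in ", path, call. = FALSE)
  }
  if (identical(meta$time_unit, "d")) times <- times * 24
  model_kind <- meta$model_kind
  species_cols <- setdiff(names(df), "time_h")
  if (is.null(model_kind)) {
    model_kind <- if (any(species_cols %in% TRI_SPECIES)) "trisaccharide"
                  else "ggm"
  }
  sp <- species_names(model_kind)
  unknown <- setdiff(species_cols, sp)
  if (length(unknown)) {
    stop("unknown species column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  initial_state <- NULL
  if (!is.null(meta$initial_state)) {
    initial_state <- as.numeric(strsplit(meta$initial_state, ",")[[1]])
  }
  timecourse_dataset(model_kind = model_kind,
                     sample_times = times,
                     observations = df[species_cols],
                     ph_profile = ph_profile,
                     initial_state = initial_state,
                     label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a time-course CSV file
#'
#' Writes a [timecourse_dataset()] or `trajectory` deterministically:
#' metadata comment lines first, species columns in the fixed ordering,
#' 10 significant digits, missing values as empty cells. A fixed input
#' yields a byte-identical file.
#'
#' @param x A `timecourse_dataset` or `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(x, path) {
  if (inherits(x, "trajectory")) {
    meta <- c(sprintf("# model_kind: %s", x$model_kind),
              "# time_unit: h")
    times <- x$times
    obs <- x$states
  } else if (inherits(x, "timecourse_dataset")) {
    meta <- c(sprintf("# model_kind: %s", x$model_kind),
              if (nzchar(x$label)) sprintf("# label: %s", x$label),
              "# time_unit: h",
              sprintf("# initial_state: %s",
                      paste(format_num(x$initial_state), collapse = ",")))
    times <- x$sample_times
    obs <- x$observations
  } else {
    stop("x must be a timecourse_dataset or trajectory", call. = FALSE)
  }
  sp <- intersect(species_names(if (inherits(x, "trajectory")) x$model_kind
                                else x$model_kind),
                  colnames(obs))
  header <- paste(c("time_h", sp), collapse = ",")
  rows <- vapply(seq_along(times), function(i) {
    paste(c(format_num(times[i]), format_num(obs[i, sp])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header, rows), con, useBytes = TRUE)
  invisible(path)
}

#' Read a pH log CSV
#'
#' Expects columns `time_h` and `ph` (comment lines allowed). A single
#' row defines a constant-pH profile.
#'
#' @param path Path to the CSV file.
#' @return A [ph_profile()].
#' @export
read_ph_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  df <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                              collapse = "\n"))
  if (!all(c("time_h", "ph") %in% names(df))) {
    stop("pH log must have columns time_h and ph", call. = FALSE)
  }
  ph_profile(df$time_h, df$ph)
}

#' Write a pH log CSV
#'
#' @param profile A [ph_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ph_log <- function(profile, path) {
  profile <- as_ph_profile(profile)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("time_h,ph",
               paste(format_num(profile$time_h), format_num(profile$ph),
                     sep = ",")),
             con, useBytes = TRUE)
  invisible(path)
}

#' Convert acetyl-peak integrals to species mole fractions
#'
#' Each acetyl methyl singlet is an equal-molar-response 3H reporter, so
#' a species' molar proxy at a time point is the *mean* of its resolvable
#' site integrals (a doubly acetylated species has two sites reporting
#' the same concentration). Fractions are then normalized per time point.
#'
#' @param peaks Data frame with columns `time_h`, `site_id`, `integral`
#'   (arbitrary units, `>= 0`).
#' @param site_map Data frame with columns `site_id`, `species`
#'   (e.g. `"c_1a"`), `position` (e.g. `"O2"`); every `site_id` in
#'   `peaks` must resolve.
#' @param convention `"acetylated"`: fractions over the acetyl-bearing
#'   species present sum to 1 at every time point (the deacetylated
#'   species is not reported). `"t0_total"`: proxies are scaled by the
#'   total proxy at the first time point and the deacetylated species
#'   (`c_1g` / `c_D`) is assigned `1 - sum(acetyl-bearing)`.
#' @param ... Passed to [timecourse_dataset()] (e.g. `ph_profile`).
#' @return A [timecourse_dataset()]. A species with no resolvable site
#'   at a time point is recorded as missing (`NA`), not zero.
#' @export
integrals_to_fractions <- function(peaks, site_map,
                                   convention = c("acetylated", "t0_total"),
                                   ...) {
  convention <- match.arg(convention)
  need <- c("time_h", "site_id", "integral")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("site_id", "species") %in% names(site_map))) {
    stop("site_map must have columns site_id, species", call. = FALSE)
  }
  if (any(peaks$integral < 0)) stop("integrals must be >= 0", call. = FALSE)
  unresolved <- setdiff(peaks$site_id, site_map$site_id)
  if (length(unresolved)) {
    stop("unresolvable site_id(s): ", paste(unresolved, collapse = ", "),
         call. = FALSE)
  }
  peaks$species <- site_map$species[match(peaks$site_id, site_map$site_id)]
  model_kind <- if (any(peaks$species %in% TRI_SPECIES)) "trisaccharide"
                else "ggm"
  sp <- species_names(model_kind)
  terminal <- TERMINAL_SPECIES[[model_kind]]
  acetyl_sp <- setdiff(sp, terminal)
  bad_sp <- setdiff(unique(peaks$species), acetyl_sp)
  if (length(bad_sp)) {
    stop("site_map assigns sites to non-acetylated or unknown species: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(peaks$time_h))
  proxy <- matrix(NA_real_, length(times), length(acetyl_sp),
                  dimnames = list(NULL, acetyl_sp))
  for (i in seq_along(times)) {
    sub <- peaks[peaks$time_h == times[i], ]
    if (!nrow(sub)) next
    m <- tapply(sub$integral, sub$species, mean)
    proxy[i, names(m)] <- m
  }
  if (all(is.na(proxy[1, ]))) {
    stop("no resolvable site at the first time point", call. = FALSE)
  }
  if (convention == "acetylated") {
    frac <- proxy / rowSums(proxy, na.rm = TRUE)
    obs <- frac
  } else {
    total0 <- sum(proxy[1, ], na.rm = TRUE)
    frac <- proxy / total0
    deac <- 1 - rowSums(frac, na.rm = TRUE)
    obs <- cbind(frac, setNames(data.frame(pmax(deac, 0)), terminal))
    obs <- as.matrix(obs)[, sp[sp %in% colnames(obs)], drop = FALSE]
  }
  first <- obs[1, ]
  init <- setNames(numeric(length(sp)), sp)
  init[names(first)[!is.na(first)]] <- first[!is.na(first)]
  timecourse_dataset(model_kind = model_kind, sample_times = times,
                     observations = obs, initial_state = init, ...)
}
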