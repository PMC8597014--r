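PARAM_NAMES <- c("k_O2_O6", "k_O3_O2", "k_O2_O3", "k_prim_hydr", "k_sec_hydr")

#' Tied rate constants of the migration/hydrolysis networks
#'
#' The five shared pseudo-first-order rate constants (h^-1, referenced to
#' pH 8) that parameterize both the trisaccharide and the GGM reaction
#' network. Reactions of the same chemical type are tied to one constant:
#'
#' * `k_O2_O6` — acetyl transfer from O2 across the glycosidic bond to the
#'   primary O6 of the neighbouring unit (1a->1b, 1e->1f; GGM B->C),
#' * `k_O3_O2` / `k_O2_O3` — the fast reversible O3/O2 exchange within a
#'   mannose unit (1b<->1c, 1d<->1e; GGM A<->B),
#' * `k_prim_hydr` — ester hydrolysis from the primary O6 position,
#' * `k_sec_hydr` — hydrolysis from the secondary O2/O3 positions.
#'
#' @param k_O2_O6,k_O3_O2,k_O2_O3,k_prim_hydr,k_sec_hydr Non-negative
#'   finite rates in h^-1 at pH 8.
#' @return An object of class `rate_constants` (named numeric vector).
#' @seealso [rate_constants_preset()] for published estimates.
#' @export
#' @examples
#' rate_constants(k_O2_O6 = 2.06e-3, k_O3_O2 = 1.88, k_O2_O3 = 1.01,
#'                k_prim_hydr = 1.93e-3, k_sec_hydr = 1.56e-3)
rate_constants <- function(k_O2_O6, k_O3_O2, k_O2_O3, k_prim_hydr,
                           k_sec_hydr) {
  k <- c(k_O2_O6 = k_O2_O6, k_O3_O2 = k_O3_O2, k_O2_O3 = k_O2_O3,
         k_prim_hydr = k_prim_hydr, k_sec_hydr = k_sec_hydr)
  if (!is.numeric(k) || length(k) != 5L) {
    stop("all five rate constants must be single numeric values",
         call. = FALSE)
  }
  if (any(!is.finite(k))) stop("rate constants must be finite", call. = FALSE)
  if (any(k < 0)) stop("rate constants must be >= 0", call. = FALSE)
  structure(k, class = "rate_constants")
}

as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) != 5L) stop("expected five rate constants", call. = FALSE)
    names(x) <- PARAM_NAMES
  }
  missing <- setdiff(PARAM_NAMES, names(x))
  if (length(missing)) {
    stop("missing rate constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(rate_constants, as.list(x[PARAM_NAMES]))
}

#' Published rate-constant estimates
#'
#' Estimates of the five tied constants at pH 8 for the trisaccharide
#' model compounds and for GGM at three concentrations (the GGM sets have
#' `k_O2_O3` locked at 1 h^-1 because the polysaccharide starts at its
#' O2/O3 equilibrium).
#'
#' @param name One of `"trisaccharide"`, `"ggm-2mg"`, `"ggm-10mg"`,
#'   `"ggm-20mg"`.
#' @return A [rate_constants()] object.
#' @export
#' @examples
#' rate_constants_preset("ggm-2mg")
rate_constants_preset <- function(name = c("trisaccharide", "ggm-2mg",
                                           "ggm-10mg", "ggm-20mg")) {
  name <- match.arg(name)
  switch(name,
    "trisaccharide" = rate_constants(2.06e-3, 1.88, 1.01, 1.93e-3, 1.56e-3),
    "ggm-2mg"  = rate_constants(1.50e-3, 1.60, 1.00, 3.72e-3, 2.60e-4),
    "ggm-10mg" = rate_constants(8.41e-4, 1.51, 1.00, 2.35e-3, 1.16e-3),
    "ggm-20mg" = rate_constants(7.08e-4, 1.56, 1.00, 2.06e-3, 1.24e-3))
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (h^-1 at pH 8):\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

#' O2-acetylated fraction at the O3/O2 migration quasi-equilibrium
#'
#' The fast O3<->O2 exchange equilibrates long before O2->O6 migration or
#' hydrolysis matter, pinning the split of acetyl groups between the O2
#' and O3 positions at `k_O3_O2 / (k_O3_O2 + k_O2_O3)`.
#'
#' @param constants A [rate_constants()] object (or coercible).
#' @return The equilibrium mole fraction of the O2-acetylated form, in
#'   (0, 1).
#' @export
#' @examples
#' equilibrium_O2_fraction(rate_constants_preset("trisaccharide")) # ~0.65
equilibrium_O2_fraction <- function(constants) {
  k <- as_rate_constants(constants)
  total <- k[["k_O3_O2"]] + k[["k_O2_O3"]]
  if (total <= 0) {
    stop("O2/O3 equilibrium undefined: both migration constants are 0",
         call. = FALSE)
  }
  k[["k_O3_O2"]] / total
}
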