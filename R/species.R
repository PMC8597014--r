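# Fixed species orderings. These define column order in every matrix,
# trajectory and CSV file the package produces.
#
# Trisaccharide species (acetylation pattern of the central/reducing units):
#   1a = central O2-Ac + O3-Ac   1b = reducing-end O6-Ac + central O3-Ac
#   1c = O6-Ac + O2-Ac           1d = O3-Ac only
#   1e = O2-Ac only              1f = O6-Ac only
#   1g = fully deacetylated
# GGM units: A = O3-acetylated, B = O2-acetylated, C = O6-acetylated,
#   D = deacetylated.
TRI_SPECIES <- c("c_1a", "c_1b", "c_1c", "c_1d", "c_1e", "c_1f", "c_1g")
GGM_SPECIES <- c("c_A", "c_B", "c_C", "c_D")

MODEL_KINDS <- c("trisaccharide", "ggm")

# Terminal (fully deacetylated) species per model; absorbing when the
# hydrolysis constants are positive.
TERMINAL_SPECIES <- c(trisaccharide = "c_1g", ggm = "c_D")

#' Species ordering for a model
#'
#' Returns the fixed, documented species ordering used for state vectors,
#' rate-matrix rows/columns, trajectory columns and CSV files.
#'
#' @param model_kind `"trisaccharide"` (species `c_1a` ... `c_1g`) or
#'   `"ggm"` (units `c_A` ... `c_D`).
#' @return Character vector of species column names.
#' @export
#' @examples
#' species_names("ggm")
species_names <- function(model_kind) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  if (model_kind == "trisaccharide") TRI_SPECIES else GGM_SPECIES
}

# Coerce a user-supplied state (named or positional) to the canonical
# ordered numeric vector, validating mole-fraction invariants.
as_state <- function(state, model_kind, tol = 1e-6) {
  sp <- species_names(model_kind)
  state <- unlist(state)
  if (!is.numeric(state)) stop("state must be numeric", call. = FALSE)
  if (!is.null(names(state)) && all(nzchar(names(state)))) {
    nm <- names(state)
    # accept both "c_1a" and bare "1a"/"A" spellings
    nm <- ifelse(nm %in% sp, nm, paste0("c_", nm))
    if (!all(nm %in% sp)) {
      stop("unknown species in state: ",
           paste(setdiff(nm, sp), collapse = ", "), call. = FALSE)
    }
    full <- setNames(numeric(length(sp)), sp)
    full[nm] <- state
    state <- full
  } else {
    if (length(state) != length(sp)) {
      stop(sprintf("state for model '%s' must have length %d, got %d",
                   model_kind, length(sp), length(state)), call. = FALSE)
    }
    names(state) <- sp
  }
  if (any(!is.finite(state))) stop("state must be finite", call. = FALSE)
  if (any(state < -tol) || any(state > 1 + tol)) {
    stop("state components must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(state, 0), 1)
}
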