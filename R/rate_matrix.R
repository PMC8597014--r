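#' Rate matrix of a migration/hydrolysis network
#'
#' Assembles the constant-coefficient matrix `K` (h^-1, at the reference
#' pH) such that the mass balances of the chosen network read
#' `dc/dt = factor(t) * K %*% c`, with `factor` the hydroxide correction
#' ([oh_correction_factor()]). Columns are source species, rows are
#' destination balances; every column sums to zero, so total mass is
#' conserved.
#'
#' Trisaccharide channels: 1a->1b and 1e->1f at `k_O2_O6`; 1b<->1c and
#' 1d<->1e at `k_O3_O2`/`k_O2_O3`; 1b->1d, 1c->1e and 1f->1g at
#' `k_prim_hydr`; 1a->1d, 1a->1e (the two parallel secondary-hydrolysis
#' channels of the doubly acetylated 1a), 1b->1f, 1c->1f, 1d->1g and
#' 1e->1g at `k_sec_hydr`. GGM channels: A<->B exchange, B->C at
#' `k_O2_O6`, A->D and B->D at `k_sec_hydr`, C->D at `k_prim_hydr`.
#'
#' @param constants A [rate_constants()] object.
#' @param model_kind `"trisaccharide"` or `"ggm"`.
#' @param k_back_1b_1a Optional O6-to-O2 back-migration rate (h^-1) for
#'   the trisaccharide 1b -> 1a step. Experimentally this step is
#'   negligible (at most a trace of 1a re-forms from 1b) and it is
#'   absent from the default model; a non-zero value here supports
#'   sensitivity studies.
#' @return A square matrix with dimnames from [species_names()], class
#'   `rate_matrix`.
#' @export
#' @examples
#' K <- build_rate_matrix(rate_constants_preset("trisaccharide"),
#'                        "trisaccharide")
#' colSums(K) # all zero
build_rate_matrix <- function(constants, model_kind, k_back_1b_1a = 0) {
  k <- as_rate_constants(constants)
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  sp <- species_names(model_kind)
  K <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  add <- function(from, to, rate) {
    from <- paste0("c_", from); to <- paste0("c_", to)
    K[to, from] <<- K[to, from] + rate
    K[from, from] <<- K[from, from] - rate
  }
  if (model_kind == "trisaccharide") {
    add("1a", "1b", k[["k_O2_O6"]])
    add("1a", "1d", k[["k_sec_hydr"]])
    add("1a", "1e", k[["k_sec_hydr"]])
    add("1b", "1c", k[["k_O3_O2"]])
    add("1c", "1b", k[["k_O2_O3"]])
    add("1b", "1d", k[["k_prim_hydr"]])
    add("1b", "1f", k[["k_sec_hydr"]])
    add("1c", "1e", k[["k_prim_hydr"]])
    add("1c", "1f", k[["k_sec_hydr"]])
    add("1d", "1e", k[["k_O3_O2"]])
    add("1e", "1d", k[["k_O2_O3"]])
    add("1e", "1f", k[["k_O2_O6"]])
    add("1d", "1g", k[["k_sec_hydr"]])
    add("1e", "1g", k[["k_sec_hydr"]])
    add("1f", "1g", k[["k_prim_hydr"]])
    if (k_back_1b_1a > 0) add("1b", "1a", k_back_1b_1a)
  } else {
    add("A", "B", k[["k_O3_O2"]])
    add("B", "A", k[["k_O2_O3"]])
    add("B", "C", k[["k_O2_O6"]])
    add("A", "D", k[["k_sec_hydr"]])
    add("B", "D", k[["k_sec_hydr"]])
    add("C", "D", k[["k_prim_hydr"]])
  }
  structure(K, class = c("rate_matrix", "matrix"), model_kind = model_kind)
}

#' Instantaneous species derivatives
#'
#' Evaluates the mass balances `factor * K %*% state` of the chosen
#' network — the right-hand side that the integrators use.
#'
#' @param state Mole-fraction state vector (named or in the fixed
#'   ordering of [species_names()]).
#' @param constants A [rate_constants()] object.
#' @param factor Hydroxide correction factor (dimensionless, `>= 0`);
#'   default 1 (reference pH).
#' @param model_kind `"trisaccharide"` or `"ggm"`.
#' @return Named derivative vector (fraction h^-1); sums to zero.
#' @export
species_rates <- function(state, constants, factor = 1,
                          model_kind = c("trisaccharide", "ggm")) {
  model_kind <- match.arg(model_kind)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0) {
    stop("factor must be a single non-negative number", call. = FALSE)
  }
  state <- as_state(state, model_kind)
  K <- build_rate_matrix(constants, model_kind)
  drop(factor * (K %*% state))
}
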