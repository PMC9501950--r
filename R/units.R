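# Energy-unit bridge between quantum-chemical totals (hartree) and the eV
# scale used by every descriptor. One factor, one place: all convention
# arithmetic (replication-mode softness and electrophilicity) must share it.

#' Hartree / electronvolt conversion factor
#'
#' The single configuration constant used throughout the package to convert
#' total electronic energies (hartree) to the eV scale of the descriptor
#' tables. CODATA-style value, overridable through [ar_config()].
#'
#' @return A length-one numeric, 27.211386 eV per hartree.
#' @export
#' @examples
#' hartree_ev_factor()
hartree_ev_factor <- function() 27.211386

#' Convert energies between hartree and electronvolt
#'
#' @param x Numeric vector of energies (hartree for `hartree_to_ev()`,
#'   eV for `ev_to_hartree()`). Must be finite.
#' @param factor Conversion factor in eV per hartree; defaults to
#'   [hartree_ev_factor()].
#' @return Numeric vector of converted energies.
#' @export
#' @examples
#' hartree_to_ev(0.263)        # 7.1566 eV
#' ev_to_hartree(hartree_to_ev(1.5))
hartree_to_ev <- function(x, factor = hartree_ev_factor()) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * factor
}

#' @rdname hartree_to_ev
#' @export
ev_to_hartree <- function(x, factor = hartree_ev_factor()) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x / factor
}
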