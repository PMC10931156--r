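#' Define a gas mixture
#'
#' @param ... Named concentrations in ppm, e.g.
#'   `gas_mixture("trans-2-hexenal" = 100)`, or a single named numeric
#'   vector. Omitted VOCs are at zero concentration.
#' @return Named numeric vector over all nine VOCs (ppm).
#' @export
gas_mixture <- function(...) {
  args <- list(...)
  conc <- if (length(args) == 1L && is.null(names(args)) &&
              !is.null(names(args[[1L]]))) args[[1L]]
          else unlist(lapply(args, unname))
  out <- setNames(numeric(9L), voc_names())
  if (length(conc)) {
    bad <- setdiff(names(conc), voc_names())
    if (length(bad)) stop("unknown VOC(s): ", paste(bad, collapse = ", "))
    if (any(conc < 0)) stop("concentrations must be >= 0")
    out[names(conc)] <- conc
  }
  out
}

#' Simulated RGB shift of dyes exposed to a gas mixture
#'
#' Each channel of each dye follows a saturating Hill dose-response,
#' `delta = max_shift * c^n / (c^n + K^n)` with Hill coefficient `n = 1`
#' by default, summed over the VOCs present and clipped channel-wise to
#' the largest single-gas maximum shift. Zero concentration gives a zero
#' shift; the magnitude is monotone non-decreasing in every
#' concentration.
#'
#' @param library A [make_dye_library()] object.
#' @param gas Named concentrations (ppm) as from [gas_mixture()].
#' @param dye Optional dye id (1-25); if given, returns a single triplet.
#' @param hill_n Hill coefficient. Default 1.
#' @return A 25 x 3 matrix of (dR, dG, dB), or a length-3 vector if `dye`
#'   is given. Units: 8-bit counts, signed.
#' @export
simulate_delta <- function(library, gas, dye = NULL, hill_n = 1) {
  stopifnot(inherits(library, "dye_library"))
  gas <- gas_mixture(gas)
  if (any(gas < 0)) stop("concentrations must be >= 0")
  delta <- matrix(0, 25L, 3L, dimnames = list(NULL, c("R", "G", "B")))
  cap <- matrix(0, 25L, 3L)
  active <- which(gas > 0)
  for (j in active) {
    frac <- gas[j]^hill_n / (gas[j]^hill_n + library$half_sat[, j]^hill_n)
    delta <- delta + library$max_delta[, j, ] * frac
    cap <- pmax(cap, abs(library$max_delta[, j, ]))
  }
  delta <- pmin(pmax(delta, -cap), cap)
  if (!is.null(dye)) {
    stopifnot(dye >= 1L, dye <= 25L)
    return(delta[dye, ])
  }
  delta
}
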