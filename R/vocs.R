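#' Characteristic volatiles of mango, peach and banana
#'
#' The nine characteristic VOCs sensed by the array, three per fruit:
#' terpenes for mango, esters/benzaldehyde for peach, and
#' ethanol/trans-2-hexenal/isoamyl acetate for banana.
#'
#' @return A data frame with columns `voc` and `fruit`.
#' @export
voc_table <- function() {
  data.frame(
    voc = c("(+)-limonene", "beta-myrcene", "3-carene",
            "benzaldehyde", "ethyl acetate", "hexyl acetate",
            "ethanol", "trans-2-hexenal", "isoamyl acetate"),
    fruit = rep(c("mango", "peach", "banana"), each = 3L),
    stringsAsFactors = FALSE
  )
}

#' Names of the nine characteristic VOCs
#' @return Character vector of length 9.
#' @export
voc_names <- function() voc_table()$voc

#' The three fruits under study
#' @return Character vector of length 3.
#' @export
fruit_names <- function() c("mango", "peach", "banana")

# Ripening-stage day boundaries per fruit: unripe [0, b1), ripe [b1, b2),
# overripe [b2, span]. Derived from firmness and sensory scoring.
fruit_stage_table <- function() {
  data.frame(
    fruit = c("banana", "mango", "peach"),
    b1 = c(2, 3, 2),
    b2 = c(6, 8, 7),
    span = c(8, 10, 10),
    stringsAsFactors = FALSE
  )
}

#' Ripeness stage at a given storage time
#'
#' Maps storage time in days onto the half-open stage intervals used for
#' labeling: banana unripe `[0, 2)`, ripe `[2, 6)`, overripe `[6, 8]`;
#' mango `[0, 3)`, `[3, 8)`, `[8, 10]`; peach `[0, 2)`, `[2, 7)`, `[7, 10]`.
#'
#' @param fruit One of `"mango"`, `"peach"`, `"banana"`.
#' @param days Storage time in days (vectorized).
#' @return Character vector: `"unripe"`, `"ripe"` or `"overripe"`.
#' @export
stage_label <- function(fruit, days) {
  tab <- fruit_stage_table()
  row <- tab[tab$fruit == match.arg(fruit, tab$fruit), ]
  if (any(days < 0 | days > row$span))
    stop("storage time outside [0, ", row$span, "] days for ", fruit)
  ifelse(days < row$b1, "unripe", ifelse(days < row$b2, "ripe", "overripe"))
}

#' The ten classification labels
#'
#' Nine fruit-by-stage classes plus `"blank"` (an unreacted array).
#' @return Character vector of length 10.
#' @export
ripeness_classes <- function() {
  c(as.vector(t(outer(fruit_names(), c("unripe", "ripe", "overripe"),
                      paste, sep = "_"))), "blank")
}

#' Volatile-emission trajectory of a ripening fruit
#'
#' Each of the fruit's three characteristic VOCs follows a saturating
#' logistic emission curve in storage time,
#' `c(t) = c_max / (1 + exp(-(t - t_mid) / tau))` (ppm), so headspace
#' concentrations rise monotonically from near zero (unripe) towards
#' `c_max` (overripe). `batch_seed` re-draws the curve parameters
#' (amplitudes, midpoints, time constants) to emulate fruit-batch
#' variation; `batch_seed = NULL` returns the nominal batch.
#'
#' @param fruit One of `"mango"`, `"peach"`, `"banana"`.
#' @param batch_seed Optional integer; jitters curve parameters to model a
#'   different fruit batch.
#' @return An object of class `ripeness_trajectory`.
#' @export
ripeness_trajectory <- function(fruit, batch_seed = NULL) {
  fruit <- match.arg(fruit, fruit_names())
  row <- fruit_stage_table()[fruit_stage_table()$fruit == fruit, ]
  vocs <- voc_table()$voc[voc_table()$fruit == fruit]
  pars <- data.frame(
    voc = vocs,
    c_max = c(400, 700, 1000),
    t_mid = c(0.8 * row$b1, (row$b1 + row$b2) / 2, 1.02 * row$b2),
    tau = rep(row$span / 12, 3L),
    stringsAsFactors = FALSE
  )
  if (!is.null(batch_seed)) {
    pars <- with_seed(derive_seed(batch_seed, paste0("batch-", fruit)), {
      # mean-preserving log-normal jitter: a re-drawn batch varies around
      # the nominal batch rather than emitting systematically more
      pars$c_max <- pars$c_max * exp(rnorm(3L, -0.25^2 / 2, 0.25))
      pars$t_mid <- pmax(0.2, pars$t_mid + rnorm(3L, 0, 0.4))
      pars$tau <- pars$tau * exp(rnorm(3L, -0.15^2 / 2, 0.15))
      pars
    })
  }
  structure(list(fruit = fruit, b1 = row$b1, b2 = row$b2, span = row$span,
                 pars = pars),
            class = "ripeness_trajectory")
}

#' Headspace VOC concentrations at a storage time
#'
#' @param traj A [ripeness_trajectory()].
#' @param days Storage time in days.
#' @return Named numeric vector of concentrations (ppm), one per VOC.
#' @export
emissions_at <- function(traj, days) {
  stopifnot(inherits(traj, "ripeness_trajectory"), days >= 0)
  p <- traj$pars
  setNames(p$c_max / (1 + exp(-(days - p$t_mid) / p$tau)), p$voc)
}

#' @export
print.ripeness_trajectory <- function(x, ...) {
  cat("Ripeness trajectory:", x$fruit,
      sprintf("(unripe < %gd, ripe < %gd, span %gd)\n", x$b1, x$b2, x$span))
  print(x$pars, row.names = FALSE)
  invisible(x)
}
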