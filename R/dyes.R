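# Dye identities for the 25-spot library. The census is fixed: two
# aldehyde/ketone-sensitive dyes, three solvatochromic dyes, three redox
# dyes, three Lewis-acidic dyes and fourteen pH indicators.
dye_identity_table <- function() {
  data.frame(
    name = c(
      "pararosaniline", "o-dianisidine",
      "nile red", "merocyanine 540", "disperse orange 3",
      "o-tolidine", "leuco malachite green", "indigo carmine",
      "Zn(II) tetraphenylporphyrin", "Cu(II) tetraphenylporphyrin",
      "Sn(IV) tetraphenylporphyrin",
      "bromophenol blue", "cresol red",
      "3,3',5,5'-tetraiodophenolsulfonphthalein", "m-cresol purple",
      "basic yellow 1", "bromocresol green", "bromocresol purple",
      "bromothymol blue", "thymol blue", "methyl red", "methyl orange",
      "phenol red", "chlorophenol red", "alizarin"),
    dye_class = c(
      rep("aldehyde_ketone", 2L), rep("solvatochromic", 3L),
      rep("redox", 3L), rep("lewis_acidic", 3L),
      rep("ph_indicator", 14L)),
    stringsAsFactors = FALSE
  )
}

# Relative affinity of each dye class for each chemical family; used to
# bias which dyes respond strongly to which VOC (cross-reactivity).
dye_class_affinity <- function() {
  fam <- c("(+)-limonene" = "terpene", "beta-myrcene" = "terpene",
           "3-carene" = "terpene", "benzaldehyde" = "aldehyde",
           "ethyl acetate" = "ester", "hexyl acetate" = "ester",
           "ethanol" = "alcohol", "trans-2-hexenal" = "aldehyde",
           "isoamyl acetate" = "ester")
  w <- rbind(
    terpene  = c(aldehyde_ketone = 0.2, solvatochromic = 4, redox = 0.5,
                 lewis_acidic = 5, ph_indicator = 0.7),
    aldehyde = c(aldehyde_ketone = 6, solvatochromic = 1, redox = 2,
                 lewis_acidic = 1, ph_indicator = 2),
    ester    = c(aldehyde_ketone = 0.3, solvatochromic = 3, redox = 0.5,
                 lewis_acidic = 1, ph_indicator = 3),
    alcohol  = c(aldehyde_ketone = 0.3, solvatochromic = 2, redox = 4,
                 lewis_acidic = 0.5, ph_indicator = 3)
  )
  list(family = fam, weights = w)
}

#' Generate a seeded 25-dye sensor library
#'
#' Builds the in-silico counterpart of a 25-dye colorimetric array: each
#' dye gets a baseline RGB color and, per VOC, a saturating response
#' parameterized by a maximum RGB shift (8-bit counts, signed) and a
#' half-saturation concentration (ppm). For every VOC at least
#' `min_responders` dyes respond strongly (maximum shift magnitude at or
#' above `strong_floor` counts) while the remaining dyes respond weakly,
#' which keeps the nine gas fingerprints mutually distinguishable.
#'
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param strong_floor Minimum Euclidean magnitude (counts) of a strong
#'   responder's maximum RGB shift. Default 40.
#' @param min_responders Minimum number of strongly responding dyes per
#'   VOC. Default 6.
#' @return An object of class `dye_library`: a list with `spec` (data
#'   frame: `dye_id` 1-25 in row-major grid order, `name`, `dye_class`,
#'   baseline `R`, `G`, `B`), `max_delta` (25 x 9 x 3 array of maximum
#'   RGB shifts) and `half_sat` (25 x 9 matrix of half-saturation
#'   concentrations, ppm).
#' @examples
#' lib <- make_dye_library(1)
#' table(lib$spec$dye_class)
#' @export
make_dye_library <- function(seed = 1L, strong_floor = 40,
                             min_responders = 6L) {
  stopifnot(min_responders >= 5L, min_responders <= 25L, strong_floor > 0)
  ids <- dye_identity_table()
  vocs <- voc_names()
  aff <- dye_class_affinity()
  with_seed(derive_seed(seed, "dye-library"), {
    spec <- data.frame(dye_id = 1:25, name = ids$name,
                       dye_class = ids$dye_class,
                       R = round(runif(25, 30, 225)),
                       G = round(runif(25, 30, 225)),
                       B = round(runif(25, 30, 225)),
                       stringsAsFactors = FALSE)
    max_delta <- array(0, dim = c(25L, 9L, 3L),
                       dimnames = list(NULL, vocs, c("R", "G", "B")))
    half_sat <- matrix(NA_real_, 25L, 9L, dimnames = list(NULL, vocs))
    rand_shift <- function(mag) {
      u <- abs(rnorm(3)) + 0.15
      s <- sample(c(-1, 1), 3L, replace = TRUE)
      mag * s * u / sqrt(sum(u^2))
    }
    for (j in seq_along(vocs)) {
      w <- aff$weights[aff$family[[vocs[j]]], spec$dye_class]
      n_resp <- sample(min_responders:(min_responders + 3L), 1L)
      resp <- sample(25L, n_resp, prob = w)
      for (i in 1:25) {
        strong <- i %in% resp
        mag <- if (strong) runif(1, strong_floor + 5, 120) else runif(1, 0, 6)
        max_delta[i, j, ] <- rand_shift(mag)
        half_sat[i, j] <- if (strong) exp(runif(1, log(20), log(200)))
                          else exp(runif(1, log(100), log(500)))
      }
    }
    structure(list(spec = spec, max_delta = max_delta, half_sat = half_sat,
                   strong_floor = strong_floor, seed = seed),
              class = "dye_library")
  })
}

#' @export
print.dye_library <- function(x, ...) {
  cat("25-dye colorimetric library (seed", x$seed, ")\n")
  print(table(x$spec$dye_class))
  invisible(x)
}
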