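#' Titratable acidity from a titration reading
#'
#' Mass percentage of citric acid from an NaOH titration of a diluted juice
#' aliquot: `TA% = C * V * K * (V0 / V1) / M * 100`. The aliquot contains
#' `V1/V0` of the total acid, so the measured acid mass is scaled back up by
#' `V0/V1` before dividing by the juice mass.
#'
#' @param V NaOH volume consumed, mL (vectorised).
#' @param C NaOH concentration, mol/L (default 0.1).
#' @param K Conversion factor to the dominant acid, g of acid per mmol NaOH
#'   (default 0.064, citric acid).
#' @param M Juice mass, g (default 10).
#' @param V0 Total diluted volume, mL (default 250).
#' @param V1 Titrated aliquot volume, mL (default 50).
#' @return Titratable acidity in percent citric acid.
#' @export
titratable_acidity <- function(V, C = 0.1, K = 0.064, M = 10, V0 = 250,
                               V1 = 50) {
  if (any(V < 0) || C <= 0 || K <= 0 || M <= 0 || V0 <= 0 || V1 <= 0)
    stop("titration quantities must be positive (V may be zero)",
         call. = FALSE)
  if (V1 > V0) stop("aliquot V1 cannot exceed total volume V0", call. = FALSE)
  C * V * K * (V0 / V1) / M * 100
}

#' Ripening index
#'
#' `RPI = ln(100 * firmness * TA / TSS)`. Lower values indicate more
#' advanced ripening and, after an impact, more severe bruise damage: both
#' firmness and acidity fall while soluble solids rise as the damaged tissue
#' ripens. Vectorised over fruits.
#'
#' @param firmness Pulp firmness (units as configured, N or g); > 0.
#' @param ta Titratable acidity, percent citric acid; > 0.
#' @param tss Total soluble solids, degrees Brix; > 0.
#' @return The ripening index (dimensionless).
#' @export
ripening_index <- function(firmness, ta, tss) {
  arg <- 100 * firmness * ta / tss
  if (any(!is.finite(arg)) || any(arg <= 0))
    stop("ripening index undefined: 100 * firmness * TA / TSS must be > 0",
         call. = FALSE)
  log(arg)
}

#' Damage-severity thresholds
#'
#' @param slight_min RPI above which a fruit counts as slightly damaged
#'   (default 7.0).
#' @param serious_max RPI below which a fruit counts as seriously damaged
#'   (default 5.0).
#' @return A validated list of thresholds.
#' @export
damage_thresholds <- function(slight_min = 7.0, serious_max = 5.0) {
  if (serious_max >= slight_min)
    stop("serious_max must be smaller than slight_min", call. = FALSE)
  list(slight_min = slight_min, serious_max = serious_max)
}

#' Damage class from the ripening index
#'
#' RPI above `slight_min` is slight damage, below `serious_max` serious, and
#' the closed interval in between (endpoints included) moderate.
#'
#' @param rpi Numeric ripening index (vectorised), finite.
#' @param thresholds A [damage_thresholds()] list.
#' @return Factor with levels `slight`, `moderate`, `serious`.
#' @export
damage_class <- function(rpi, thresholds = damage_thresholds()) {
  if (any(!is.finite(rpi))) stop("rpi must be finite", call. = FALSE)
  out <- ifelse(rpi > thresholds$slight_min, "slight",
         ifelse(rpi < thresholds$serious_max, "serious", "moderate"))
  factor(out, levels = c("slight", "moderate", "serious"))
}
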