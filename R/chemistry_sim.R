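#' Reference means and SDs for the blood-chemistry panel
#'
#' Per-condition normal parameters for the measured analytes at rest
#' (baseline), at the end of exhaustive exercise (peak) and at 2, 4 and 6
#' minutes of recovery.  Lactate, sodium, potassium, calcium, chloride,
#' PCO2, hydrogen ion, bicarbonate and haemoglobin follow the published
#' cohort values for maximal cycling exercise in healthy young men.
#' Glucose and PO2 were not reported for that cohort; the values here are
#' textbook-plausible defaults for arterialised venous blood and are marked
#' `invented = TRUE`.
#'
#' @return data frame with columns `analyte`, `unit`, `condition`, `mean`,
#'   `sd`, `invented`.
#' @export
chemistry_reference <- function() {
  conds <- c("baseline", "peak", "rec2", "rec4", "rec6")
  tab <- list(
    ##            unit          means                          sds                      invented
    La      = list("mmol/L", c(1.1, 10.8, 15.2, 15.6, 15.3), c(0.4, 3.1, 2.2, 2.2, 2.2), FALSE),
    Na      = list("mmol/L", c(141, 148, 146, 144, 143),     c(1, 2, 1, 1, 1),           FALSE),
    K       = list("mmol/L", c(4.0, 5.4, 4.1, 3.8, 3.8),     c(0.2, 0.6, 0.2, 0.2, 0.2), FALSE),
    Ca      = list("mmol/L", c(1.23, 1.31, 1.28, 1.26, 1.24), c(0.03, 0.04, 0.03, 0.03, 0.03), FALSE),
    Cl      = list("mmol/L", c(105, 108, 107, 106, 106),     c(1, 2, 2, 1, 1),           FALSE),
    PCO2    = list("mmHg",   c(44.9, 52.8, 36.3, 33.8, 33.2), c(4.1, 9.9, 3.9, 3.2, 2.7), FALSE),
    H       = list("nmol/L", c(40.8, 61.8, 63.8, 65.4, 65.1), c(2.2, 8.6, 7.0, 7.2, 7.1), FALSE),
    HCO3    = list("mmol/L", c(25.7, 18.4, 14.8, 14.0, 13.9), c(1.1, 2.1, 1.5, 1.4, 1.5), FALSE),
    Hb      = list("g/dL",   c(15.4, 16.7, 16.7, 16.6, 16.4), c(1.1, 1.0, 1.0, 1.0, 1.0), FALSE),
    glucose = list("mmol/L", c(5.0, 5.8, 6.0, 6.1, 6.0),     c(0.4, 0.8, 0.8, 0.8, 0.8), TRUE),
    PO2     = list("mmHg",   c(90, 100, 98, 96, 95),         c(8, 10, 9, 9, 9),          TRUE)
  )
  do.call(rbind, lapply(names(tab), function(a) {
    data.frame(analyte = a, unit = tab[[a]][[1]], condition = conds,
               mean = tab[[a]][[2]], sd = tab[[a]][[3]],
               invented = tab[[a]][[4]], stringsAsFactors = FALSE)
  }))
}

#' Simulate a blood-chemistry panel for a study
#'
#' Draws one row per (participant, condition) from independent normal
#' distributions with the per-condition means and SDs of
#' [chemistry_reference()], truncated at the physiological floor of zero.
#' pH is derived from the drawn hydrogen-ion concentration
#' (`pH = 9 - log10([H+])`), the strong ion difference from the drawn
#' electrolytes ([strong_ion_difference()]) and the blood volume change
#' from each participant's own baseline haemoglobin
#' ([delta_blood_volume()]).
#'
#' @param design a [study_design()]; supplies participants and conditions
#'   (conditions absent from the reference table are rejected).
#' @param seed integer RNG seed.
#' @param reference reference table, by default [chemistry_reference()].
#' @param sd_scale multiplier on all SDs (0 collapses every row to the
#'   condition means).
#' @return data frame of class `dd_chemistry` with one row per participant
#'   per condition and the 14 panel variables.
#' @export
generate_chemistry_table <- function(design, seed = design$master_seed,
                                     reference = chemistry_reference(),
                                     sd_scale = 1) {
  stopifnot(inherits(design, "dd_design"))
  conds <- design$conditions
  stop_if_not(all(conds %in% reference$condition),
              "conditions missing from the reference table: %s",
              paste(setdiff(conds, reference$condition), collapse = ", "))
  n <- design$n_participants
  analytes <- unique(reference$analyte)

  panel <- withr::with_seed(as.integer(seed), {
    rows <- expand.grid(participant = seq_len(n), condition = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$participant, match(rows$condition, conds)), ]
    for (a in analytes) {
      ref <- reference[reference$analyte == a, ]
      mu <- ref$mean[match(rows$condition, ref$condition)]
      sd <- ref$sd[match(rows$condition, ref$condition)] * sd_scale
      rows[[a]] <- pmax(0, stats::rnorm(nrow(rows), mu, sd))
    }
    rows
  })

  panel$pH <- 9 - log10(panel$H)
  panel$SID <- strong_ion_difference(panel$Na, panel$K, panel$Ca,
                                     panel$Cl, panel$La)
  hb_rest <- panel$Hb[match(paste(panel$participant, conds[1]),
                            paste(panel$participant, panel$condition))]
  panel$dBV <- delta_blood_volume(hb_rest, panel$Hb)
  rownames(panel) <- NULL
  class(panel) <- c("dd_chemistry", "data.frame")
  panel
}

## The 14 panel variables of the chemistry analysis.
chem_panel_vars <- function() {
  c("pH", "PCO2", "PO2", "K", "Na", "Ca", "La", "Cl", "HCO3",
    "glucose", "Hb", "H", "SID", "dBV")
}
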