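# Published landscape tables, transcribed as in-code fixtures. Areas are
# km^2 of forest in 2012 by habitat class; `ambiguous = TRUE` marks
# landscapes whose per-class cells could not be transcribed unambiguously
# from the source (their class cells are NA and they are excluded from
# class-level arithmetic; their landscape totals and loss percentages are
# unambiguous and retained).

#' Forest area by landscape and habitat class (2012)
#'
#' Long-format table: 15 tiger landscapes x 5 habitat classes, with the
#' per-landscape `ambiguous` transcription flag.
#'
#' @return Data frame: `landscape`, `epoch`, `class`, `area_km2`,
#'   `ambiguous`.
#' @export
sumatra_forest_areas <- function() {
  cls <- habitat_classes()
  # montane, lowland-hill primary, peat primary, lowland-hill degraded,
  # peat degraded; NA rows are ambiguous in the source
  cells <- list(
    "Ulu Masen"                  = c(NA, NA, NA, NA, NA),
    "Gunung Leuser"              = c(NA, NA, NA, NA, NA),
    "Sibolga & Bt Toru"          = c(5521, 0, 0, 2711, 23),
    "Bt Gadis/Rimbo-Panti"       = c(4563, 579, 0, 3693, 130),
    "Rimbang Baling & Bt Hari"   = c(1659, 1710, 0, 3143, 0),
    "Kerinci Seblat"             = c(10330, 3010, 0, 4017, 6),
    "Bk Barisan Selatan"         = c(3188, 1128, 0, 1397, 0),
    "Bk Tiga Puluh"              = c(0, 0, 0, 2842, 0),
    "Senepis-Buluhala"           = c(0, 0, 732, 87, 2309),
    "Kuala Kampar & Keremutan"   = c(0, 0, 659, 108, 5500),
    "Tesso Nilo"                 = c(0, 0, 0, 740, 125),
    "Bk Dua Belas"               = c(0, 0, 0, 391, 0),
    "Berbak"                     = c(0, 0, 0, 687, 2721),
    "Harapan"                    = c(0, 0, 0, 1108, 0),
    "Way Kambas"                 = c(0, 0, 0, 1312, 9)
  )
  out <- do.call(rbind, lapply(names(cells), function(l) {
    data.frame(landscape = l, epoch = 2012, class = cls,
               area_km2 = cells[[l]],
               ambiguous = anyNA(cells[[l]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-landscape forest totals and 12-year deforestation
#'
#' @return Data frame: `landscape`, `total_2012_thousand_km2`,
#'   `loss_12yr_pct`.
#' @export
sumatra_forest_summary <- function() {
  data.frame(
    landscape = c("Ulu Masen", "Gunung Leuser", "Sibolga & Bt Toru",
                  "Bt Gadis/Rimbo-Panti", "Rimbang Baling & Bt Hari",
                  "Kerinci Seblat", "Bk Barisan Selatan", "Bk Tiga Puluh",
                  "Senepis-Buluhala", "Kuala Kampar & Keremutan",
                  "Tesso Nilo", "Bk Dua Belas", "Berbak", "Harapan",
                  "Way Kambas"),
    total_2012_thousand_km2 = c(6.8, 21.3, 8.3, 9.0, 6.5, 17.4, 5.7, 2.8,
                                3.1, 6.3, 0.9, 0.4, 3.4, 1.1, 1.3),
    loss_12yr_pct = c(8.8, 7.6, 4.5, 7.8, 24.5, 12.8, 9.7, 39.1, 40.9,
                      38.8, 55.3, 36.9, 11.7, 7.2, 5.1),
    stringsAsFactors = FALSE
  )
}

#' Island-wide habitat-class totals and per-class loss
#'
#' @return Data frame: `class`, `area_2012_thousand_km2`, `loss_pct`.
#' @export
sumatra_class_totals <- function() {
  data.frame(
    class = habitat_classes(),
    area_2012_thousand_km2 = c(43.9, 8.9, 1.4, 29.1, 10.9),
    loss_pct = c(3.9, 23.1, 35.5, 20.5, 34.8),
    stringsAsFactors = FALSE
  )
}

#' Published landscape population estimates (2000 and 2012)
#'
#' Adults, breeding females, and the +/- 1 SE range per landscape, plus
#' the priority flag (the seven landscapes highlighted for conservation)
#' and core-forest areas used by the secure-source-population rule.
#'
#' @return Data frame with one row per landscape.
#' @export
sumatra_population_table <- function() {
  data.frame(
    landscape = c("Ulu Masen", "Gunung Leuser", "Sibolga & Bt Toru",
                  "Bt Gadis/Rimbo-Panti", "Rimbang Baling & Bt Hari",
                  "Kerinci Seblat", "Bk Barisan Selatan", "Bk Tiga Puluh",
                  "Senepis-Buluhala", "Kuala Kampar & Keremutan",
                  "Tesso Nilo", "Bk Dua Belas", "Berbak", "Harapan",
                  "Way Kambas"),
    adults_2012 = c(45, 140, 52, 61, 53, 122, 41, 22, 14, 26, 6, 3, 16, 8, 10),
    adults_2000 = c(51, 154, 54, 67, 71, 145, 46, 36, 23, 42, 13, 5, 17, 9, 10),
    bf_2012 = c(16, 48, 18, 21, 18, 42, 14, 7, 5, 9, 2, 1, 5, 3, 3),
    bf_2000 = c(17, 53, 18, 23, 25, 50, 16, 12, 8, 15, 5, 2, 6, 3, 3),
    tigers_minus_1se = c(24, 74, 27, 32, 28, 65, 22, 12, 7, 14, 3, 2, 8, 4, 5),
    tigers_plus_1se = c(66, 206, 76, 89, 77, 180, 61, 32, 20, 38, 9, 4, 23, 12, 15),
    priority = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 8)),
    stringsAsFactors = FALSE
  )
}

#' New heritage-site SCR densities, forest and non-forest
#'
#' The three 2014 survey sites with their forest and adjacent non-forest
#' density estimates (per 100 km^2) and standard errors.
#'
#' @return Data frame: `site`, `habitat`, `density`, `se_density`.
#' @export
heritage_site_densities <- function() {
  data.frame(
    site = rep(c("Gunung Leuser", "Kerinci Seblat", "Bukit Barisan Selatan"),
               each = 2),
    habitat = rep(c("forest", "nonforest"), 3),
    density = c(1.32, 0.56, 0.74, 0.21, 1.94, 0.38),
    se_density = c(0.81, 0.93, 0.65, 0.36, 0.91, 0.78),
    stringsAsFactors = FALSE
  )
}
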