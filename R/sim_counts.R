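#' Generate synthetic per-animal marker count tables
#'
#' Draws per-animal, per-region marker summaries from normal distributions.
#' Default means and SDs for OMP are the study's printed endo/ecto
#' percentages (WT endo 65.29 +/- 5.10, ecto 71.11 +/- 3.95; 5xFAD endo
#' 62.70 +/- 4.04, ecto 52.74 +/- 5.25).  TH+ periglomerular cells per 5
#' glomeruli are in relative units with the reported dorsal/ventral
#' normalized means (WT 1.00 / 1.67; 5xFAD 1.13 / 0.61).  Ki67 and TUNEL
#' encode the reported ectoturbinate fold changes (proliferation halved,
#' apoptosis doubled in 5xFAD) on plausible base rates.
#'
#' @param n_per_group animals per genotype (default 6).
#' @param seed integer seed.
#' @param effect_scale multiplier in \[0,1\] applied to all genotype x
#'   region effects: 1 keeps the defaults, 0 sets every 5xFAD mean equal to
#'   its WT counterpart (null data for calibration).
#' @return a `data.frame` of class `"count_table"` with columns
#'   `animal_id`, `genotype`, `region`, `marker`, `value`, `unit`; one row
#'   per animal x region x marker, values truncated at 0.
#' @export
generate_count_tables <- function(n_per_group = 6L, seed = 1L,
                                  effect_scale = 1) {
  spec <- count_table_spec()
  nr <- nrow(spec)
  parts <- with_seed(seed, lapply(c("WT", "5xFAD"), function(g) {
    if (g == "WT") {
      mu <- spec$mean_wt
      sd <- spec$sd_wt
    } else {
      mu <- spec$mean_wt + effect_scale * (spec$mean_tg - spec$mean_wt)
      sd <- spec$sd_tg
    }
    a <- rep(seq_len(n_per_group), each = nr)
    data.frame(
      animal_id = sprintf("%s_%02d", sub("x", "", g), a),
      genotype = g,
      region = rep(spec$region, n_per_group),
      marker = rep(spec$marker, n_per_group),
      value = pmax(rnorm(nr * n_per_group, mu, sd), 0),
      unit = rep(spec$unit, n_per_group))
  }))
  out <- do.call(rbind, parts)
  class(out) <- c("count_table", "data.frame")
  out
}

count_table_spec <- function() {
  data.frame(
    marker = c("OMP", "OMP", "TH", "TH", "Ki67", "Ki67", "TUNEL", "TUNEL"),
    region = c("endo", "ecto", "dorsal", "ventral",
               "endo", "ecto", "endo", "ecto"),
    mean_wt = c(65.29, 71.11, 1.00, 1.67, 10, 10, 4, 4),
    sd_wt   = c(5.10, 3.95, 0.15, 0.15, 1.5, 1.5, 0.9, 0.9),
    mean_tg = c(62.70, 52.74, 1.13, 0.61, 10, 5, 4, 8),
    sd_tg   = c(4.04, 5.25, 0.15, 0.15, 1.5, 1.5, 0.9, 0.9),
    unit = c("%OMP", "%OMP", "cells per 5 glomeruli",
             "cells per 5 glomeruli", "cells/mm2", "cells/mm2",
             "cells/mm2", "cells/mm2"))
}
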