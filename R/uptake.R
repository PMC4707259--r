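# Per-plant total Zn uptake from shoot measurements.
#
# Root Zn concentrations of soil-grown rice cannot be measured reliably
# (soil contamination inflates them to 30-100 ug/g), so root Zn content is
# estimated from shoot Zn concentration via a fixed root:shoot concentration
# ratio calibrated in nutrient solution, where root concentrations run about
# 70% above shoot concentrations.

#' Estimate total per-plant Zn uptake from shoot measurements
#'
#' Total Zn = measured shoot content + estimated root content, with root Zn
#' concentration taken as `root_factor` times the shoot concentration:
#' `conc * shoot_dw/1000 + root_factor * conc * root_dw/1000` (dry weights
#' in mg, concentrations in ug g^-1, result in ug plant^-1).
#'
#' @param shoot_zn_conc Shoot Zn concentration, ug g^-1 (vectorized).
#' @param shoot_dw_mg Shoot dry weight, mg plant^-1.
#' @param root_dw_mg Root dry weight, mg plant^-1 (0 or NA for shoot-only).
#' @param root_factor Root:shoot Zn concentration ratio; default 1.7 from
#'   the nutrient-solution calibration.
#' @return Total Zn content, ug plant^-1.
#' @examples
#' estimate_total_uptake(10, 100, 50) # 1.0 + 0.85 = 1.85 ug
#' @export
estimate_total_uptake <- function(shoot_zn_conc, shoot_dw_mg, root_dw_mg = 0,
                                  root_factor = 1.7) {
  stopifnot(length(root_factor) == 1L, is.finite(root_factor),
            root_factor > 0)
  root_dw_mg[is.na(root_dw_mg)] <- 0
  if (any(shoot_zn_conc < 0, na.rm = TRUE) ||
      any(shoot_dw_mg < 0, na.rm = TRUE) || any(root_dw_mg < 0)) {
    stop("concentrations and dry weights must be non-negative")
  }
  shoot_zn_conc * shoot_dw_mg / 1000 +
    root_factor * shoot_zn_conc * root_dw_mg / 1000
}

#' Net Zn uptake since transplanting
#'
#' Plant Zn content minus the Zn content of the transplanted seedling.
#' Negative values (content dropped below the seedling reserve) indicate a
#' retranslocation-dominated phase with no net uptake and are flagged.
#'
#' @param content_now Current plant Zn content, ug plant^-1 (vectorized).
#' @param seedling_content Seedling Zn content at transplanting, ug plant^-1.
#' @return Net uptake, ug plant^-1, with a logical attribute
#'   `"retranslocation_dominated"` marking negative entries.
#' @export
net_uptake <- function(content_now, seedling_content) {
  if (any(content_now < 0, na.rm = TRUE) ||
      any(seedling_content < 0, na.rm = TRUE)) {
    stop("Zn contents must be non-negative")
  }
  out <- content_now - seedling_content
  structure(out, retranslocation_dominated = !is.na(out) & out < 0)
}

#' Append a derived total-Zn-uptake column to a tidy observation table
#'
#' Row-wise [estimate_total_uptake()], emitting `total_zn_uptake_ug`.  A
#' measured root Zn concentration column, if present, is ignored with a
#' warning: in soil-grown plants it reflects soil contamination.
#'
#' @param obs Tidy observation data frame (see [read_table()]).
#' @param root_factor Passed to [estimate_total_uptake()].
#' @return `obs` with an added `total_zn_uptake_ug` column.
#' @export
add_total_uptake <- function(obs, root_factor = 1.7) {
  stopifnot(is.data.frame(obs))
  if ("root_zn_ug_per_g" %in% names(obs)) {
    warning("measured root Zn concentrations are ignored ",
            "(soil contamination); root content is estimated from shoot ",
            "concentration instead", call. = FALSE)
  }
  obs$total_zn_uptake_ug <- estimate_total_uptake(
    obs$shoot_zn_ug_per_g, obs$shoot_dw_mg, obs$root_dw_mg,
    root_factor = root_factor)
  obs
}
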