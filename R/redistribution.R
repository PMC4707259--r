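# Shoot-to-root Zn retranslocation metrics for the root-excision
# solution-culture experiment: roots are cut at the crown on day 0 and the
# plants regrow roots for 13 d in Zn-free solution, so any Zn found in the
# regrown roots at harvest must have been retranslocated from the shoot.

#' One group-level record of the root-regrowth experiment
#'
#' @param group Group label (`"tolerant"` / `"sensitive"`).
#' @param dap Days after root excision (0 = excision day, 13 = harvest).
#' @param root_zn_content,shoot_zn_content Zn contents, ug plant^-1.
#' @param root_dw_mg,shoot_dw_mg Dry weights, mg plant^-1.
#' @param root_zn_conc,shoot_zn_conc Zn concentrations, ug g^-1.
#' @param crown_roots Crown root count.
#' @param zn_free_solution Was the culture solution Zn-free?  Required for
#'   the retranslocation identity.
#' @return A `redistribution_record` list.
#' @export
redistribution_record <- function(group, dap, root_zn_content,
                                  shoot_zn_content, root_dw_mg, shoot_dw_mg,
                                  root_zn_conc = NA_real_,
                                  shoot_zn_conc = NA_real_,
                                  crown_roots = NA_real_,
                                  zn_free_solution = TRUE) {
  vals <- c(root_zn_content, shoot_zn_content, root_dw_mg, shoot_dw_mg)
  if (any(vals < 0, na.rm = TRUE)) stop("quantities must be non-negative")
  # contents must agree with conc x DW where both are given
  chk <- function(content, conc, dw, what) {
    if (!is.na(conc) && !is.na(content) && dw > 0) {
      if (abs(content - conc * dw / 1000) > 0.02 * max(content, 1e-9)) {
        stop(what, " Zn content (", content, " ug) inconsistent with conc x ",
             "DW (", signif(conc * dw / 1000, 4), " ug)")
      }
    }
  }
  chk(root_zn_content, root_zn_conc, root_dw_mg, "root")
  chk(shoot_zn_content, shoot_zn_conc, shoot_dw_mg, "shoot")
  structure(list(group = group, dap = dap,
                 root_zn_content = root_zn_content,
                 shoot_zn_content = shoot_zn_content,
                 root_dw_mg = root_dw_mg, shoot_dw_mg = shoot_dw_mg,
                 root_zn_conc = root_zn_conc, shoot_zn_conc = shoot_zn_conc,
                 crown_roots = crown_roots,
                 zn_free_solution = isTRUE(zn_free_solution)),
            class = "redistribution_record")
}

#' Zn retranslocated from shoot to regrown roots
#'
#' Equals the harvest root Zn content: with roots fully excised at day 0 and
#' no Zn in the solution, all root Zn at harvest originated in the shoot.
#'
#' @param rec_harvest A harvest-day [redistribution_record()].
#' @return Retranslocated Zn, ug plant^-1.
#' @export
retranslocated_zn <- function(rec_harvest) {
  stopifnot(inherits(rec_harvest, "redistribution_record"))
  if (!rec_harvest$zn_free_solution) {
    stop("retranslocation identity requires a Zn-free solution; ",
         "this record reports external Zn supply")
  }
  if (rec_harvest$dap <= 0) {
    stop("retranslocation is read from a post-excision harvest record ",
         "(dap > 0), got dap = ", rec_harvest$dap)
  }
  rec_harvest$root_zn_content
}

#' Percent excess of the tolerant over the sensitive group
#'
#' `100 * (tolerant/sensitive - 1)`, e.g. 0.45 vs 0.27 ug -> 67%.
#'
#' @param metric_tol,metric_sens Group metric values; `metric_sens > 0`.
#' @param display Round half-up to integer percent (default TRUE).
#' @return Percent excess.
#' @export
group_excess <- function(metric_tol, metric_sens, display = TRUE) {
  if (any(metric_sens <= 0)) stop("baseline (sensitive) metric must be > 0")
  pct <- 100 * (metric_tol / metric_sens - 1)
  if (display) round_half_up(pct, 0) else pct
}

#' Root:shoot allocation ratios for dry weight and Zn content
#'
#' @param rec_tol,rec_sens Harvest [redistribution_record()]s for the two
#'   groups.
#' @return Data frame with rows `dw` and `zn_content`: the root:shoot ratio
#'   per group and the tolerant/sensitive percent excess (unrounded and
#'   display-rounded).
#' @export
allocation_ratios <- function(rec_tol, rec_sens) {
  stopifnot(inherits(rec_tol, "redistribution_record"),
            inherits(rec_sens, "redistribution_record"))
  ratio <- function(rec, num, den) {
    if (rec[[den]] <= 0) stop("zero shoot quantity in group '",
                              rec$group, "'")
    rec[[num]] / rec[[den]]
  }
  rows <- rbind(
    data.frame(measure = "dw",
               tolerant = ratio(rec_tol, "root_dw_mg", "shoot_dw_mg"),
               sensitive = ratio(rec_sens, "root_dw_mg", "shoot_dw_mg")),
    data.frame(measure = "zn_content",
               tolerant = ratio(rec_tol, "root_zn_content",
                                "shoot_zn_content"),
               sensitive = ratio(rec_sens, "root_zn_content",
                                 "shoot_zn_content")))
  rows$excess_pct <- group_excess(rows$tolerant, rows$sensitive,
                                  display = FALSE)
  rows$excess_pct_display <- round_half_up(rows$excess_pct, 0)
  rows
}

#' Group-mean redistribution report from plant-level solution records
#'
#' Aggregates plant-level solution-experiment rows into group means by day,
#' computes retranslocation and allocation metrics, and attaches LSD flags
#' from [anova_lsd()] comparing the groups at each day.
#'
#' @param sol Data frame of solution-experiment plants: columns `group`,
#'   `replicate`, `dap`, `root_zn_ug`, `shoot_zn_ug`, `root_dw_mg`,
#'   `shoot_dw_mg`, `crown_roots` (as produced by [generate_solution()]).
#' @param alpha LSD significance level.
#' @return List with `means` (group x day means of each metric plus total Zn
#'   content), `lsd` (per metric/day: F p-value and the LSD, or "ns"),
#'   `retranslocation` (group values, excess percent), `allocation`
#'   (from [allocation_ratios()] on harvest means).
#' @export
redistribution_report <- function(sol, alpha = 0.05) {
  stopifnot(is.data.frame(sol),
            all(c("group", "dap", "root_zn_ug", "shoot_zn_ug",
                  "root_dw_mg", "shoot_dw_mg") %in% names(sol)))
  sol$total_zn_ug <- sol$root_zn_ug + sol$shoot_zn_ug
  metrics <- c("root_zn_ug", "shoot_zn_ug", "total_zn_ug",
               "root_dw_mg", "shoot_dw_mg", "crown_roots")
  metrics <- intersect(metrics, names(sol))
  means <- lapply(metrics, function(m) {
    s <- group_summary(sol, by = c("dap", "group"), var = m)
    s$metric <- m
    s
  })
  means <- do.call(rbind, means)
  lsd <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(sort(unique(sol$dap)), function(d) {
      sub <- sol[sol$dap == d, ]
      res <- anova_lsd(sub[[m]], sub$group, alpha = alpha)
      data.frame(metric = m, dap = d, f_pvalue = res$f_pvalue,
                 lsd = if (res$protected) NA_real_ else res$lsd_05,
                 flag = if (res$protected) "ns" else
                   if (res$f_pvalue <= 0.01) "**" else "*")
    }))
  }))
  harvest_dap <- max(sol$dap)
  gm <- function(g, m, d) mean(sol[[m]][sol$group == g & sol$dap == d])
  mk_rec <- function(g) {
    redistribution_record(
      group = g, dap = harvest_dap,
      root_zn_content = gm(g, "root_zn_ug", harvest_dap),
      shoot_zn_content = gm(g, "shoot_zn_ug", harvest_dap),
      root_dw_mg = gm(g, "root_dw_mg", harvest_dap),
      shoot_dw_mg = gm(g, "shoot_dw_mg", harvest_dap))
  }
  rec_tol <- mk_rec("tolerant")
  rec_sens <- mk_rec("sensitive")
  retr_tol <- retranslocated_zn(rec_tol)
  retr_sens <- retranslocated_zn(rec_sens)
  list(means = means, lsd = lsd,
       retranslocation = data.frame(
         tolerant_ug = retr_tol, sensitive_ug = retr_sens,
         excess_pct = group_excess(retr_tol, retr_sens)),
       allocation = allocation_ratios(rec_tol, rec_sens))
}
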