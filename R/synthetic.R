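# Synthetic plant-level datasets for the three experiment designs the
# analysis pipeline expects: the randomized-block Zn-deficiency field trial
# (2 tolerant + 3 sensitive genotypes, 4 replicates, samplings at 7/14/21/28
# DAT), the planting-density trial (1/2/4/8 plants per hill), and the
# root-excision solution-culture redistribution experiment.
#
# Effect sizes are imposed, not emergent: group trait trajectories follow
# the bundled offset-exponential curves, density effects are anchored at a
# 10-fold per-plant uptake increase and a 2.5-fold root-biomass increase at
# four plants per hill, and noise is multiplicative lognormal (mean 1) per
# plant per trait.

# mean-1 multiplicative lognormal noise
.lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# run expr with a locally-seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the synthetic trial generators
#'
#' Defaults encode the emulated design: 2 tolerant + 3 sensitive genotypes,
#' 4 replicates in randomized blocks, weekly samplings 7--28 DAT, group
#' trajectories from [default_group_curves()], 10% per-trait CV, a shoot Zn
#' concentration plateau of 12 ug g^-1 under deficiency, and density-effect
#' anchors of 10-fold uptake / 2.5-fold root biomass at 4 plants per hill
#' with saturation at 8.
#'
#' @param seed Integer RNG seed.
#' @param genotypes Named character vector mapping genotype to group.
#' @param n_reps Replicates (= blocks) per genotype and treatment.
#' @param sampling_dat Sampling days after transplanting.
#' @param group_curves Named list of [efficiency_curve()]s per group.
#' @param noise_cv Per-trait coefficient of variation of the multiplicative
#'   lognormal plant-level noise.
#' @param shoot_conc_minusZn Mean deficient-plot shoot Zn concentration from
#'   14 DAT onward, ug g^-1 (the deficiency plateau).
#' @param shoot_conc_pre Mean shoot Zn concentration at 7 DAT, ug g^-1
#'   (seedling reserves not yet diluted by growth).
#' @param seedling_zn_ug Seedling total Zn content at transplanting, ug.
#' @param pre_drop Fractional drop of total Zn content between 7 and 14 DAT
#'   (the no-uptake retranslocation phase).
#' @param root_factor Root:shoot Zn concentration ratio used when deriving
#'   dry weights (so the uptake-estimation rule inverts the generator).
#' @param rs_ratio Root:shoot dry-weight ratio.
#' @param crown_base Crown roots per plant at 14 DAT, by group.
#' @param crown_rate Relative crown-root emergence rate, d^-1.
#' @param specific_root_length Root length per unit surface area, cm cm^-2.
#' @param diameter_class_fractions Length fractions in the fine/lateral/crown
#'   diameter classes.
#' @param density_effects List: `uptake_fold_at_4`, `rootdw_fold_at_4`,
#'   `saturation_at_8` (fold interpolation is log-linear in density).
#' @param density_base Per-plant baselines at density 1 and 28 DAT:
#'   `uptake_ug` and `root_dw_mg`, each named by group; 21-DAT values are
#'   scaled down by `density_time_factor`.
#' @param density_time_factor Ratio of 21-DAT to 28-DAT baseline values.
#' @param solution_targets Group-mean anchors for the redistribution
#'   experiment: day-0 total Zn, day-0 root Zn fraction, tissue Zn
#'   concentrations, retranslocated Zn, crown-root counts.
#' @param contamination Optional length-2 range (ug g^-1); when set, a
#'   spurious measured root Zn concentration column contaminated to this
#'   range is added to field output (downstream code must ignore it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genotypes = c("TOL-1" = "tolerant",
                                     "TOL-2" = "tolerant",
                                     "SEN-1" = "sensitive",
                                     "SEN-2" = "sensitive",
                                     "SEN-3" = "sensitive"),
                       n_reps = 4L,
                       sampling_dat = c(7, 14, 21, 28),
                       group_curves = default_group_curves(),
                       noise_cv = 0.10,
                       shoot_conc_minusZn = 12,
                       shoot_conc_pre = 31,
                       seedling_zn_ug = 1.8,
                       pre_drop = 0.05,
                       root_factor = 1.7,
                       rs_ratio = 0.20,
                       crown_base = c(tolerant = 26.5, sensitive = 20.1),
                       crown_rate = 0.04,
                       specific_root_length = 16,
                       diameter_class_fractions = c(fine = 0.5, mid = 0.3,
                                                    coarse = 0.2),
                       density_effects = list(uptake_fold_at_4 = 10,
                                              rootdw_fold_at_4 = 2.5,
                                              saturation_at_8 = TRUE),
                       density_base = list(
                         uptake_ug = c(tolerant = 1.2, sensitive = 0.6),
                         root_dw_mg = c(tolerant = 25, sensitive = 20)),
                       density_time_factor = 0.5,
                       solution_targets = list(
                         total0_ug = c(tolerant = 1.33, sensitive = 1.11),
                         root_frac0 = 0.25,
                         root_conc0 = c(tolerant = 55.6, sensitive = 49.1),
                         shoot_conc0 = c(tolerant = 39.9, sensitive = 36.8),
                         retrans_ug = c(tolerant = 0.45, sensitive = 0.27),
                         shoot_conc13 = c(tolerant = 12.5, sensitive = 14.4),
                         root_conc13 = c(tolerant = 22.6, sensitive = 24.7),
                         crown0 = c(tolerant = 14.0, sensitive = 12.4),
                         crown13 = c(tolerant = 16.0, sensitive = 13.0)),
                       contamination = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_reps >= 1L, noise_cv >= 0, root_factor > 0, rs_ratio > 0,
            all(unlist(genotypes) %in% c("tolerant", "sensitive")),
            all(c("tolerant", "sensitive") %in% names(group_curves)),
            density_effects$uptake_fold_at_4 > 0,
            density_effects$rootdw_fold_at_4 > 0)
  frac <- diameter_class_fractions
  stopifnot(abs(sum(frac) - 1) < 1e-9, all(frac >= 0))
  structure(as.list(environment()), class = "sim_config")
}

# Noiseless group-level truth for one field sampling day.
.field_truth <- function(cfg, group, dat) {
  t <- dat_to_model_time(dat)
  ec <- cfg$group_curves[[group]]
  uptake <- if (t >= 0) eval_curve(ec$uptake, t) else 0
  content <- if (t >= 0) cfg$seedling_zn_ug + uptake
             else cfg$seedling_zn_ug * (1 + cfg$pre_drop * (-t / 7))
  conc <- if (t >= 0) cfg$shoot_conc_minusZn else cfg$shoot_conc_pre
  list(uptake = uptake, content = content, conc = conc,
       rsa = eval_curve(ec$rsa, t),
       crown = cfg$crown_base[[group]] * exp(cfg$crown_rate * t))
}

#' Generate a synthetic Zn-deficiency field trial
#'
#' One plant per row, tidy schema (see [read_table()]).  Group-mean trait
#' trajectories follow the configured curves at model time `dat - 14`; total
#' Zn content before 14 DAT is back-filled as the (slightly declining)
#' seedling reserve, reflecting the no-uptake retranslocation phase after
#' transplanting.  Shoot and root dry weights are partitioned so that
#' [estimate_total_uptake()] applied to the generated concentration and dry
#' weights reproduces the generated plant Zn content exactly.
#'
#' @param cfg A [sim_config()].
#' @return Tidy data frame, one row per plant per sampling.
#' @export
generate_field <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    grid <- expand.grid(genotype = names(cfg$genotypes),
                        replicate = seq_len(cfg$n_reps),
                        dat = cfg$sampling_dat,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    group <- unname(unlist(cfg$genotypes)[grid$genotype])
    truth <- Map(function(g, d) .field_truth(cfg, g, d), group, grid$dat)
    content <- vapply(truth, `[[`, numeric(1), "content") * .lnoise(n, cfg$noise_cv)
    conc <- vapply(truth, `[[`, numeric(1), "conc") * .lnoise(n, cfg$noise_cv)
    rsa <- vapply(truth, `[[`, numeric(1), "rsa") * .lnoise(n, cfg$noise_cv)
    crown <- vapply(truth, `[[`, numeric(1), "crown") * .lnoise(n, cfg$noise_cv)
    # invert the uptake-estimation rule: content = conc*(sdw + rf*rdw)/1000
    shoot_dw <- 1000 * content / (conc * (1 + cfg$root_factor * cfg$rs_ratio))
    root_dw <- cfg$rs_ratio * shoot_dw
    total_len <- rsa * cfg$specific_root_length
    fr <- cfg$diameter_class_fractions
    out <- data.frame(
      experiment = "field", genotype = grid$genotype, group = group,
      treatment = "minusZn", dat = grid$dat, replicate = grid$replicate,
      hill_density = 1L,
      shoot_dw_mg = shoot_dw, root_dw_mg = root_dw,
      shoot_zn_ug_per_g = conc,
      crown_roots = crown, rsa_cm2 = rsa,
      root_len_fine_cm = total_len * fr[["fine"]],
      root_len_mid_cm = total_len * fr[["mid"]],
      root_len_coarse_cm = total_len * fr[["coarse"]],
      stringsAsFactors = FALSE)
    if (!is.null(cfg$contamination)) {
      out$root_zn_ug_per_g <- stats::runif(n, cfg$contamination[1],
                                           cfg$contamination[2])
    }
    out <- out[order(out$dat, out$genotype, out$replicate), ]
    rownames(out) <- NULL
    out
  })
}

# log-linear density fold interpolation with optional plateau at 8
.density_fold <- function(density, fold_at_4, saturate8 = TRUE) {
  d <- pmin(density, if (saturate8) 4 else density)
  exp(log(fold_at_4) * log(d) / log(4))
}

#' Generate a synthetic planting-density trial
#'
#' Per-plant Zn uptake scales with hill density by log-linear interpolation
#' between 1x at one plant per hill and the configured fold at four, with a
#' plateau at eight; per-plant root biomass scales likewise with its own
#' (smaller) fold, so uptake per unit root biomass rises with density.
#'
#' @param cfg A [sim_config()].
#' @return Tidy data frame (same schema as [generate_field()]), sampled at
#'   21 and 28 DAT, `hill_density` in {1, 2, 4, 8}.
#' @export
generate_density <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 1L, {
    grid <- expand.grid(genotype = names(cfg$genotypes),
                        replicate = seq_len(cfg$n_reps),
                        dat = c(21, 28), hill_density = c(1L, 2L, 4L, 8L),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    group <- unname(unlist(cfg$genotypes)[grid$genotype])
    de <- cfg$density_effects
    tf <- ifelse(grid$dat == 28, 1, cfg$density_time_factor)
    uptake <- cfg$density_base$uptake_ug[group] * tf *
      .density_fold(grid$hill_density, de$uptake_fold_at_4,
                    de$saturation_at_8) * .lnoise(n, cfg$noise_cv)
    root_dw <- cfg$density_base$root_dw_mg[group] * tf *
      .density_fold(grid$hill_density, de$rootdw_fold_at_4,
                    de$saturation_at_8) * .lnoise(n, cfg$noise_cv)
    conc <- 11 * .lnoise(n, cfg$noise_cv)
    # shoot DW set so the uptake-estimation rule returns the target uptake
    shoot_dw <- pmax(1000 * uptake / conc - cfg$root_factor * root_dw, 1)
    rsa <- root_dw * 1.5  # cm2 per mg root, coarse allometric stand-in
    total_len <- rsa * cfg$specific_root_length
    fr <- cfg$diameter_class_fractions
    out <- data.frame(
      experiment = "density", genotype = grid$genotype, group = group,
      treatment = "minusZn", dat = grid$dat, replicate = grid$replicate,
      hill_density = grid$hill_density,
      shoot_dw_mg = shoot_dw, root_dw_mg = root_dw,
      shoot_zn_ug_per_g = conc,
      crown_roots = cfg$crown_base[group] * .lnoise(n, cfg$noise_cv),
      rsa_cm2 = rsa,
      root_len_fine_cm = total_len * fr[["fine"]],
      root_len_mid_cm = total_len * fr[["mid"]],
      root_len_coarse_cm = total_len * fr[["coarse"]],
      stringsAsFactors = FALSE)
    out <- out[order(out$hill_density, out$dat, out$genotype,
                     out$replicate), ]
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic root-excision redistribution experiment
#'
#' Plant-level records at day 0 (excision) and day 13 (harvest) of the
#' Zn-free solution-culture experiment.  Day-13 root Zn is drawn as a
#' retranslocated fraction of each plant's own day-0 shoot Zn, so shoot Zn
#' loss always covers root Zn gain (no Zn creation), and dry weights are
#' derived from contents and target tissue concentrations.
#'
#' @param cfg A [sim_config()].
#' @return Data frame, one row per plant per day: `experiment`, `group`,
#'   `genotype`, `replicate`, `dap`, `root_zn_ug`, `shoot_zn_ug`,
#'   `root_dw_mg`, `shoot_dw_mg`, `root_zn_conc_ug_per_g`,
#'   `shoot_zn_conc_ug_per_g`, `crown_roots`, `zn_free_solution`.
#' @export
generate_solution <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- cfg$solution_targets
  .with_seed(cfg$seed + 2L, {
    grid <- expand.grid(genotype = names(cfg$genotypes),
                        replicate = seq_len(cfg$n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    group <- unname(unlist(cfg$genotypes)[grid$genotype])
    total0 <- st$total0_ug[group] * .lnoise(n, cfg$noise_cv)
    root0 <- st$root_frac0 * total0
    shoot0 <- total0 - root0
    # retranslocated fraction of each plant's own shoot reserve, capped so
    # the shoot can never lose more Zn than it holds
    mean_shoot0 <- (1 - st$root_frac0) * st$total0_ug[group]
    frac <- pmin(st$retrans_ug[group] / mean_shoot0 *
                   .lnoise(n, cfg$noise_cv), 0.95)
    root13 <- frac * shoot0
    shoot13 <- shoot0 - root13
    d0 <- data.frame(
      experiment = "solution", group = group, genotype = grid$genotype,
      replicate = grid$replicate, dap = 0,
      root_zn_ug = root0, shoot_zn_ug = shoot0,
      root_dw_mg = 1000 * root0 / st$root_conc0[group],
      shoot_dw_mg = 1000 * shoot0 / st$shoot_conc0[group],
      root_zn_conc_ug_per_g = st$root_conc0[group],
      shoot_zn_conc_ug_per_g = st$shoot_conc0[group],
      crown_roots = st$crown0[group] * .lnoise(n, cfg$noise_cv),
      zn_free_solution = TRUE, stringsAsFactors = FALSE)
    d13 <- data.frame(
      experiment = "solution", group = group, genotype = grid$genotype,
      replicate = grid$replicate, dap = 13,
      root_zn_ug = root13, shoot_zn_ug = shoot13,
      root_dw_mg = 1000 * root13 / st$root_conc13[group],
      shoot_dw_mg = 1000 * shoot13 / st$shoot_conc13[group],
      root_zn_conc_ug_per_g = st$root_conc13[group],
      shoot_zn_conc_ug_per_g = st$shoot_conc13[group],
      crown_roots = st$crown13[group] * .lnoise(n, cfg$noise_cv),
      zn_free_solution = TRUE, stringsAsFactors = FALSE)
    out <- rbind(d0, d13)
    out <- out[order(out$dap, out$genotype, out$replicate), ]
    rownames(out) <- NULL
    out
  })
}
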