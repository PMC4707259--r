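# Tidy-table I/O, curve serialization, and the pipeline driver.

#' Tidy observation table schema
#'
#' Exact header of the plant-level CSV consumed and produced by the
#' package: one row per plant per sampling, UTF-8, comma-separated, '.'
#' decimal, empty field = missing.
#'
#' @format Character vector of column names.
#' @export
TIDY_COLUMNS <- c("experiment", "genotype", "group", "treatment", "dat",
                  "replicate", "hill_density", "shoot_dw_mg", "root_dw_mg",
                  "shoot_zn_ug_per_g", "crown_roots", "rsa_cm2",
                  "root_len_fine_cm", "root_len_mid_cm",
                  "root_len_coarse_cm")

.TIDY_NUMERIC <- setdiff(TIDY_COLUMNS,
                         c("experiment", "genotype", "group", "treatment"))

#' Read a tidy plant-observation CSV
#'
#' Validates the header against [TIDY_COLUMNS] (extra columns are kept),
#' checks numeric columns, non-negative measures and the allowed `dat` /
#' `hill_density` levels, and reports violations with row numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(TIDY_COLUMNS, names(obs))
  if (length(missing_cols)) {
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in .TIDY_NUMERIC) {
    if (!is.numeric(obs[[cn]])) {
      bad <- which(!is.na(obs[[cn]]) &
                     is.na(suppressWarnings(as.numeric(obs[[cn]]))))
      stop("non-numeric values in '", cn, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  measures <- c("shoot_dw_mg", "root_dw_mg", "shoot_zn_ug_per_g",
                "crown_roots", "rsa_cm2", "root_len_fine_cm",
                "root_len_mid_cm", "root_len_coarse_cm")
  for (cn in measures) {
    bad <- which(!is.na(obs[[cn]]) & obs[[cn]] < 0)
    if (length(bad)) {
      stop("negative '", cn, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  bad <- which(!is.na(obs$hill_density) &
                 !obs$hill_density %in% c(1, 2, 4, 8))
  if (length(bad)) {
    stop("hill_density outside {1,2,4,8} at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  obs
}

#' Write a tidy plant-observation CSV
#'
#' @param obs Data frame containing at least [TIDY_COLUMNS].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obs, path) {
  stopifnot(all(TIDY_COLUMNS %in% names(obs)))
  utils::write.csv(obs, path, row.names = FALSE, na = "")
  invisible(path)
}

.curve_to_list <- function(curve, group_id = NULL) {
  c(list(scale = curve$scale, rate = curve$rate, offset = curve$offset,
         role = curve$role, origin_dat = ORIGIN_DAT),
    if (!is.null(group_id)) list(group_id = group_id))
}

#' Serialize efficiency curves to JSON
#'
#' Writes a list of paired uptake/RSA curve records
#' `{scale, rate, offset, role, group_id, origin_dat}` at full precision.
#'
#' @param curves Named list of [efficiency_curve()]s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_curves_json <- function(curves, path) {
  recs <- unlist(lapply(curves, function(ec) {
    list(.curve_to_list(ec$uptake, ec$group_id),
         .curve_to_list(ec$rsa, ec$group_id))
  }), recursive = FALSE)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read efficiency curves from JSON
#'
#' @param path JSON file written by [write_curves_json()] (or hand-authored
#'   in the same record format).
#' @return Named list of [efficiency_curve()]s, one per `group_id`.
#' @export
read_curves_json <- function(path) {
  recs <- jsonlite::read_json(path)
  groups <- unique(vapply(recs, `[[`, character(1), "group_id"))
  out <- lapply(groups, function(g) {
    mine <- Filter(function(r) r$group_id == g, recs)
    pick <- function(role) {
      r <- Filter(function(x) x$role == role, mine)
      if (length(r) != 1L) {
        stop("expected exactly one '", role, "' curve for group '", g, "'")
      }
      if (!is.null(r[[1]]$origin_dat) && r[[1]]$origin_dat != ORIGIN_DAT) {
        stop("curve for group '", g, "' uses time origin ",
             r[[1]]$origin_dat, " DAT; this package fixes the origin at ",
             ORIGIN_DAT, " DAT")
      }
      exp_curve(r[[1]]$scale, r[[1]]$rate, r[[1]]$offset, role = role)
    }
    efficiency_curve(pick("uptake"), pick("rsa"), group_id = g)
  })
  names(out) <- groups
  out
}

# group-mean uptake/RSA series on the fitting window, from tidy field rows
.field_series <- function(obs, seedling_zn_ug, root_factor) {
  obs <- add_total_uptake(obs, root_factor = root_factor)
  obs <- obs[obs$dat >= ORIGIN_DAT, ]
  if (!nrow(obs)) stop("no observations at or after ", ORIGIN_DAT, " DAT")
  obs$net_uptake_ug <- as.numeric(net_uptake(obs$total_zn_uptake_ug,
                                             seedling_zn_ug))
  lapply(split(obs, obs$group), function(sub) {
    up <- group_summary(sub, by = "dat", var = "net_uptake_ug")
    rs <- group_summary(sub, by = "dat", var = "rsa_cm2")
    g <- sub$group[1]
    list(uptake = group_series(g, dat_to_model_time(up$dat),
                               pmax(up$mean, 0), "uptake", se = up$se),
         rsa = group_series(g, dat_to_model_time(rs$dat), rs$mean, "rsa",
                            se = rs$se))
  })
}

#' Fit group efficiency curves from a tidy field table
#'
#' Aggregates plant rows to group means per sampling day (14 DAT onward),
#' derives net Zn uptake via [add_total_uptake()] and [net_uptake()], and
#' fits the uptake and RSA curves per group.
#'
#' @param obs Tidy field observations (see [read_table()]).
#' @param seedling_zn_ug Seedling Zn content at transplanting, ug plant^-1.
#' @param root_factor Root:shoot Zn concentration ratio.
#' @return Named list of [efficiency_curve()]s by group.
#' @export
fit_field_curves <- function(obs, seedling_zn_ug = 1.8, root_factor = 1.7) {
  series <- .field_series(obs, seedling_zn_ug, root_factor)
  lapply(series, function(s) fit_group_pair(s$uptake, s$rsa))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Stages (selected automatically from the experiments present unless
#' `config$stages` is given): `fit` (group curve fits from field data),
#' `efficiency` (RE sampled on a daily grid), `counterfactual` (attribution
#' table at the configured horizons), `density` (fold-change table),
#' `redistribution` (solution-experiment report), `summary` (group
#' mean +/- SE tables).  All outputs are deterministic given the config.
#'
#' @param config A list, or path to a JSON file, with elements: `input`
#'   (tidy CSV path) and/or `simulate` (list with `experiment` =
#'   field/density/solution and optional [sim_config()] overrides such as
#'   `seed`, `noise_cv`), `outdir` (default `"rootzn-report"`), `stages`
#'   (optional character vector), `seedling_zn_ug`, `root_factor`,
#'   `horizons` (model days, default `c(7, 14)`).
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else config_path <- NULL
  stopifnot(is.list(config))
  outdir <- config$outdir %||% "rootzn-report"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seedling <- config$seedling_zn_ug %||% 1.8
  root_factor <- config$root_factor %||% 1.7
  horizons <- config$horizons %||% c(7, 14)

  logf <- file.path(outdir, "log.txt")
  log_lines <- c(
    paste0("rootzn ", as.character(utils::packageVersion("rootzn"))),
    paste0("R ", getRversion()))

  obs <- NULL
  if (!is.null(config$input)) {
    obs <- read_table(config$input)
    log_lines <- c(log_lines,
                   paste0("input: ", config$input, " md5=",
                          unname(tools::md5sum(config$input))))
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    experiment <- sim$experiment %||% "field"
    cfg_args <- sim[setdiff(names(sim), "experiment")]
    cfg <- do.call(sim_config, cfg_args)
    gen <- switch(experiment, field = generate_field,
                  density = generate_density, solution = generate_solution,
                  stop("unknown experiment '", experiment, "'"))
    obs <- gen(cfg)
    log_lines <- c(log_lines, paste0("simulated: ", experiment,
                                     " seed=", cfg$seed,
                                     " noise_cv=", cfg$noise_cv))
  } else stop("config needs either 'input' or 'simulate'")

  experiments <- unique(obs$experiment)
  stages <- config$stages %||% c(
    if ("field" %in% experiments) c("fit", "efficiency", "counterfactual",
                                    "summary"),
    if ("density" %in% experiments) "density",
    if ("solution" %in% experiments) "redistribution")

  out <- list(observations = obs, outdir = outdir)
  curves <- NULL

  if ("fit" %in% stages) {
    curves <- fit_field_curves(obs[obs$experiment == "field", ],
                               seedling_zn_ug = seedling,
                               root_factor = root_factor)
    write_curves_json(curves, file.path(outdir, "fitted_curves.json"))
    out$curves <- curves
    log_lines <- c(log_lines, "stage fit: ok")
  }
  if ("efficiency" %in% stages) {
    if (is.null(curves)) stop("stage 'efficiency' requires stage 'fit'")
    tgrid <- seq(ANALYSIS_WINDOW[1], ANALYSIS_WINDOW[2], by = 1)
    re <- do.call(rbind, lapply(curves, function(ec) {
      data.frame(group = ec$group_id, t_d = tgrid, dat = tgrid + ORIGIN_DAT,
                 re_ug_cm2_d = root_efficiency(ec, tgrid))
    }))
    rownames(re) <- NULL
    utils::write.csv(re, file.path(outdir, "re_grid.csv"),
                     row.names = FALSE)
    out$re_grid <- re
    log_lines <- c(log_lines, "stage efficiency: ok")
  }
  if ("counterfactual" %in% stages) {
    if (is.null(curves)) stop("stage 'counterfactual' requires stage 'fit'")
    if (!all(c("tolerant", "sensitive") %in% names(curves))) {
      stop("counterfactual stage needs 'tolerant' and 'sensitive' groups")
    }
    attr_tab <- attribution_table(curves$tolerant, curves$sensitive,
                                  horizons = horizons)
    utils::write.csv(attr_tab, file.path(outdir, "attribution.csv"),
                     row.names = FALSE)
    out$attribution <- attr_tab
    log_lines <- c(log_lines, "stage counterfactual: ok")
  }
  if ("summary" %in% stages) {
    fld <- add_total_uptake(obs[obs$experiment == "field", ],
                            root_factor = root_factor)
    summ <- do.call(rbind, lapply(
      c("shoot_dw_mg", "shoot_zn_ug_per_g", "total_zn_uptake_ug",
        "crown_roots", "rsa_cm2"),
      function(v) {
        s <- group_summary(fld, by = c("group", "dat"), var = v)
        s$trait <- v
        s
      }))
    utils::write.csv(summ, file.path(outdir, "group_summary.csv"),
                     row.names = FALSE)
    out$summary <- summ
    log_lines <- c(log_lines, "stage summary: ok")
  }
  if ("density" %in% stages) {
    dens <- add_total_uptake(obs[obs$experiment == "density", ],
                             root_factor = root_factor)
    folds <- density_folds(dens)
    utils::write.csv(folds, file.path(outdir, "density_folds.csv"),
                     row.names = FALSE)
    out$density <- folds
    log_lines <- c(log_lines, "stage density: ok")
  }
  if ("redistribution" %in% stages) {
    sol <- obs[obs$experiment == "solution", ]
    rep_ <- redistribution_report(sol)
    utils::write.csv(rep_$means, file.path(outdir, "redistribution.csv"),
                     row.names = FALSE)
    out$redistribution <- rep_
    log_lines <- c(log_lines, "stage redistribution: ok")
  }
  if (!is.null(config_path)) {
    log_lines <- c(log_lines, paste0("config md5=",
                                     unname(tools::md5sum(config_path))))
  }
  writeLines(log_lines, logf)
  message(paste(log_lines, collapse = "\n"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
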