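# Group summaries, ANOVA-protected LSD, trait correlations, and
# planting-density fold-change analysis.

#' Mean, standard error and n per group cell
#'
#' @param obs Data frame of observations.
#' @param by Character vector of grouping column names.
#' @param var Name of the value column to summarise.
#' @return Data frame with the grouping columns plus `mean`, `se`, `n`.
#'   Cells with no data simply do not appear (missing, not zero).
#' @export
group_summary <- function(obs, by, var) {
  stopifnot(is.data.frame(obs), all(by %in% names(obs)), var %in% names(obs))
  keys <- obs[by]
  v <- obs[[var]]
  idx <- split(seq_along(v), keys, drop = TRUE)
  rows <- lapply(idx, function(i) {
    x <- v[i]
    x <- x[!is.na(x)]
    n <- length(x)
    cbind(obs[i[1], by, drop = FALSE],
          data.frame(mean = if (n) mean(x) else NA_real_,
                     se = if (n > 1) stats::sd(x) / sqrt(n) else
                       if (n == 1) 0 else NA_real_,
                     n = n))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' One-way ANOVA with protected LSD pairwise comparisons
#'
#' Fisher's protected least significant difference: pairwise genotype
#' comparisons are made only when the one-way ANOVA F-test is significant at
#' `alpha`; otherwise no pair is declared different.  With a balanced design
#' (n per genotype) the LSD is `t(1 - alpha/2, df_error) * sqrt(2 MSE / n)`;
#' with unequal n each pair uses its own standard error.
#'
#' @param values Numeric response vector.
#' @param genotype Factor (or coercible) of genotype labels.
#' @param alpha Significance level (default 0.05).
#' @return An `lsd_result` list: `f_stat`, `f_pvalue`, `lsd_05` (balanced
#'   LSD in trait units, NA if unbalanced), `mse`, `df_error`,
#'   `pairwise_significant` (data frame of genotype pairs), `protected`
#'   (TRUE when the F-test gate stopped pairwise testing), `means`.
#' @export
anova_lsd <- function(values, genotype, alpha = 0.05) {
  genotype <- factor(genotype)
  keep <- !is.na(values)
  values <- values[keep]
  genotype <- droplevels(genotype[keep])
  k <- nlevels(genotype)
  if (k < 2L) stop("need at least 2 genotypes")
  n_i <- table(genotype)
  if (any(n_i < 2L)) stop("need at least 2 replicates per genotype")
  df_err <- length(values) - k
  if (df_err <= 0L) stop("zero error degrees of freedom")
  fit <- stats::aov(values ~ genotype)
  # zero-residual (e.g. noiseless synthetic) data: the F-test is degenerate
  # but the group separation is real; keep base R's result, drop its warning
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  f_stat <- an[["F value"]][1]
  f_p <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]
  means <- tapply(values, genotype, mean)
  balanced <- length(unique(n_i)) == 1L
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  lsd <- if (balanced) tcrit * sqrt(2 * mse / n_i[[1]]) else NA_real_
  pairs <- data.frame(g1 = character(), g2 = character(),
                      diff = numeric(), lsd = numeric())
  protected <- TRUE
  if (is.finite(f_p) && f_p <= alpha) {
    protected <- FALSE
    lv <- levels(genotype)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      lsd_ij <- tcrit * sqrt(mse * (1 / n_i[[i]] + 1 / n_i[[j]]))
      d <- abs(means[[i]] - means[[j]])
      if (d > lsd_ij) {
        pairs <- rbind(pairs, data.frame(g1 = lv[i], g2 = lv[j],
                                         diff = d, lsd = lsd_ij))
      }
    }
  }
  structure(list(f_stat = f_stat, f_pvalue = f_p, lsd_05 = lsd, mse = mse,
                 df_error = df_err, alpha = alpha, means = means,
                 pairwise_significant = pairs, protected = protected),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  star <- if (!is.finite(x$f_pvalue) || x$f_pvalue > x$alpha) "ns"
          else if (x$f_pvalue <= 0.01) "**" else "*"
  cat(sprintf("<lsd_result> F = %.3g, p = %.3g (%s), LSD(%.2g) = %.3g\n",
              x$f_stat, x$f_pvalue, star, x$alpha, x$lsd_05))
  if (nrow(x$pairwise_significant)) {
    cat("  significant pairs:",
        paste(x$pairwise_significant$g1, x$pairwise_significant$g2,
              sep = "~", collapse = ", "), "\n")
  } else cat("  no significant pairs (protected)\n")
  invisible(x)
}

#' Pairwise Pearson correlation matrix of traits
#'
#' @param traits Data frame of numeric trait columns.
#' @param min_n Minimum complete pairs per entry (default 3).
#' @return Symmetric correlation matrix with unit diagonal; entries backed
#'   by fewer than `min_n` complete pairs, or involving a zero-variance
#'   trait, are `NA` (flagged with a warning).
#' @export
pearson_matrix <- function(traits, min_n = 3L) {
  stopifnot(is.data.frame(traits), ncol(traits) >= 2L)
  m <- as.matrix(traits)
  stopifnot(is.numeric(m))
  p <- ncol(m)
  r <- diag(1, p)
  dimnames(r) <- list(colnames(m), colnames(m))
  flagged <- character()
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    ok <- stats::complete.cases(m[, c(i, j)])
    xi <- m[ok, i]; xj <- m[ok, j]
    if (sum(ok) < min_n || stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      flagged <- c(flagged, paste0(colnames(m)[i], "~", colnames(m)[j]))
    } else {
      r[i, j] <- r[j, i] <- stats::cor(xi, xj)
    }
  }
  if (length(flagged)) {
    warning("undefined correlations (too few pairs or zero variance): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }
  r
}

#' Planting-density fold changes in uptake, root biomass and efficiency
#'
#' Summarises the density experiment per hill density: per-plant Zn uptake,
#' per-plant root dry weight, root efficiency expressed as Zn taken up per
#' unit final root biomass, and per-hill totals, each as a fold change
#' relative to single-plant hills.  The efficiency fold equals the uptake
#' fold divided by the root-DW fold.
#'
#' @param obs Observation data frame with `hill_density`, `root_dw_mg` and a
#'   `total_zn_uptake_ug` column (see [add_total_uptake()]).
#' @return Data frame with one row per density; columns `hill_density`,
#'   `uptake_ug`, `root_dw_mg`, `uptake_per_hill_ug`, `uptake_fold`,
#'   `root_dw_fold`, `efficiency_fold`, `uptake_fold_display` (nearest
#'   integer), `efficiency_fold_display`.
#' @export
density_folds <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("hill_density", "root_dw_mg", "total_zn_uptake_ug") %in%
                  names(obs)))
  dens <- sort(unique(obs$hill_density))
  if (!1 %in% dens) stop("baseline density 1 plant/hill missing")
  agg <- function(v) tapply(v, obs$hill_density, mean, na.rm = TRUE)
  up <- agg(obs$total_zn_uptake_ug)
  rdw <- agg(obs$root_dw_mg)
  out <- data.frame(hill_density = dens,
                    uptake_ug = as.numeric(up),
                    root_dw_mg = as.numeric(rdw))
  out$uptake_per_hill_ug <- out$uptake_ug * out$hill_density
  base_u <- out$uptake_ug[out$hill_density == 1]
  base_r <- out$root_dw_mg[out$hill_density == 1]
  out$uptake_fold <- out$uptake_ug / base_u
  out$root_dw_fold <- out$root_dw_mg / base_r
  out$efficiency_fold <- out$uptake_fold / out$root_dw_fold
  out$uptake_fold_display <- round_half_up(out$uptake_fold, 0)
  out$efficiency_fold_display <- round_half_up(out$efficiency_fold, 0)
  out
}

#' Proportion of fine roots by length
#'
#' Fraction of total root length in the fine-lateral diameter class
#' (< 0.15 mm), out of fine + lateral (0.15-0.40 mm) + crown (> 0.40 mm).
#'
#' @param fine,mid,coarse Root length per diameter class, cm (vectorized).
#' @return Fraction in `[0, 1]`; `NA` (with a warning) where the total
#'   length is zero.
#' @export
percent_fine_roots <- function(fine, mid, coarse) {
  if (any(c(fine, mid, coarse) < 0, na.rm = TRUE)) {
    stop("root lengths must be non-negative")
  }
  total <- fine + mid + coarse
  zero <- !is.na(total) & total == 0
  if (any(zero)) {
    warning("zero total root length in ", sum(zero),
            " observation(s); fraction undefined", call. = FALSE)
    total[zero] <- NA_real_
  }
  fine / total
}

#' Round half away from zero
#'
#' Display rounding matching hand-reported integer percentages (R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
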