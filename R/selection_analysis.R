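#' ENc-plot table
#'
#' One row per gene with defined ENc and GC3s, giving the observed ENc, the
#' mutation-only expectation on Wright's curve, and the relative deviation
#' `(ENc_exp - ENc) / ENc_exp`. Positive deviation places the gene below the
#' curve, the classical signature of selection on synonymous sites. Genes
#' with undefined inputs are dropped (their ids are returned in the
#' `"dropped"` attribute).
#'
#' @param records data.frame from [gene_cub_table()].
#' @return data.frame: gene_id, taxon, category, gc3s, enc, enc_expected,
#'   deviation.
#' @export
enc_plot_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  ok <- !is.na(records$enc) & !is.na(records$gc3s)
  out <- records[ok, c("gene_id", "taxon", "category", "gc3s", "enc"),
                 drop = FALSE]
  out$enc_expected <- enc_expected(out$gc3s)
  out$deviation <- (out$enc_expected - out$enc) / out$enc_expected
  rownames(out) <- NULL
  attr(out, "dropped") <- records$gene_id[!ok]
  out
}

#' Neutrality-plot regression
#'
#' Ordinary least squares of GC12 (mean of GC1 and GC2) on GC3 across genes,
#' with the Pearson correlation and its two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. A slope near 1 indicates that
#' one mutational pressure drives all three codon positions; a slope near 0
#' indicates third-position usage decoupled from positions 1-2, i.e.
#' selection.
#'
#' @param records data.frame from [gene_cub_table()] (needs `gc12`, `gc3`).
#' @param pool_label label recorded on the fit.
#' @return list of class `neutrality_fit`: slope, abs_slope, intercept,
#'   pearson_r, p_value, n_genes, pool_label.
#' @export
neutrality_regression <- function(records, pool_label = "all") {
  ok <- !is.na(records$gc12) & !is.na(records$gc3)
  x <- records$gc3[ok]
  y <- records$gc12[ok]
  n <- length(x)
  if (n < 3L) stop("neutrality regression needs at least 3 genes, got ", n)
  if (stats::var(x) == 0) stop("zero variance in GC3; regression undefined")
  fit <- stats::lm(y ~ x)
  # constant GC12 has no defined correlation: report r = 0 (no association)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  p <- if (stats::var(y) == 0) 1 else if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         abs_slope = abs(unname(stats::coef(fit)[2])),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = r, p_value = p, n_genes = n, pool_label = pool_label),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality fit [%s]: GC12 = %.4f + %.4f * GC3  (|slope| %.3f, r %.3f, p %.3g, n %d)\n",
              x$pool_label, x$intercept, x$slope, x$abs_slope,
              x$pearson_r, x$p_value, x$n_genes))
  invisible(x)
}

#' Neutrality fits per pool
#'
#' Runs [neutrality_regression()] for every combination of the grouping
#' columns, mirroring the per-category, per-genus-pair layout used in
#' chloroplast CUB studies, plus an all-genes fit per group of `pool_by[1]`.
#'
#' @param records data.frame from [gene_cub_table()].
#' @param pool_by character vector of grouping columns (default
#'   `c("taxon", "category")`).
#' @return data.frame, one row per pool: pool columns plus slope, abs_slope,
#'   intercept, pearson_r, p_value, n_genes.
#' @export
neutrality_by_pool <- function(records, pool_by = c("taxon", "category")) {
  stopifnot(all(pool_by %in% names(records)))
  key <- interaction(records[pool_by], drop = TRUE, sep = ":")
  groups <- split(records, key)
  fit_row <- function(g, label) {
    f <- tryCatch(neutrality_regression(g, label), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(pool = label, slope = f$slope, abs_slope = f$abs_slope,
               intercept = f$intercept, pearson_r = f$pearson_r,
               p_value = f$p_value, n_genes = f$n_genes,
               stringsAsFactors = FALSE)
  }
  rows <- Map(fit_row, groups, names(groups))
  # add an all-genes fit per top-level group
  top <- split(records, records[[pool_by[1]]])
  rows <- c(rows, Map(fit_row, top, paste0(names(top), ":all")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Interpret the mutation-vs-selection diagnostics
#'
#' Rule-based summary combining the three diagnostics: the neutrality slope
#' (|slope| < `slope_selection` labels the pool selection-dominant,
#' |slope| > `slope_mutation` mutation-dominant, otherwise mixed -- heuristic
#' conveniences, echoed in the output), the fraction of genes strictly below
#' the expected-ENc curve, and the mean PR2 displacement vector from the
#' parity point (0.5, 0.5).
#'
#' @param fit a `neutrality_fit`.
#' @param enc_rows data.frame from [enc_plot_table()].
#' @param pr2_points data.frame with columns `pr2_x`, `pr2_y`.
#' @param slope_selection,slope_mutation the heuristic slope thresholds.
#' @return list: label, slope, abs_slope, thresholds, frac_below_curve,
#'   pr2_displacement (named vector dx, dy).
#' @export
interpret_diagnostics <- function(fit, enc_rows, pr2_points,
                                  slope_selection = 0.3,
                                  slope_mutation = 0.7) {
  s <- fit$abs_slope
  label <- if (s < slope_selection) "selection-dominant"
           else if (s > slope_mutation) "mutation-dominant"
           else "mixed"
  frac_below <- mean(enc_rows$deviation > 0)
  dx <- mean(pr2_points$pr2_x, na.rm = TRUE) - 0.5
  dy <- mean(pr2_points$pr2_y, na.rm = TRUE) - 0.5
  list(
    label = label,
    slope = fit$slope,
    abs_slope = s,
    thresholds = c(selection = slope_selection, mutation = slope_mutation),
    frac_below_curve = frac_below,
    pr2_displacement = c(dx = dx, dy = dy)
  )
}
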