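#' Mean of a scalar map over a region of interest
#'
#' Arithmetic mean over the masked voxels with defined (non-`NA`) values.
#'
#' @param map 3D scalar array ([scalar_map] or bare).
#' @param mask Logical 3D mask.
#' @return The ROI mean.
#' @export
roi_mean <- function(map, mask) {
  if (!all(dim(map) == dim(mask)))
    stop("map and mask geometry differ")
  vals <- map[as.logical(mask)]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("empty ROI: mask contains no valid voxels")
  mean(vals)
}

#' Normalize an ROI value to a reference-region value
#'
#' Expressed as a percentage, `100 * roi / ref`; the reference is
#' typically the splenium-like region whose robust anisotropic signature
#' anchors the comparison across timepoints.
#'
#' @param roi ROI summary value.
#' @param ref Reference-region summary value (> 0).
#' @return Percentage of the reference.
#' @export
normalize_to_reference <- function(roi, ref) {
  if (any(ref <= 0)) stop("invalid reference: reference value must be > 0")
  100 * roi / ref
}

stats_result <- function(test, comparison, statistic, df, p,
                         p_adjusted = NA_real_, alpha = 0.05) {
  data.frame(test = test, comparison = comparison,
             statistic = statistic, df = df,
             p_raw = p, p_adj = p_adjusted,
             significant = (if (all(is.na(p_adjusted))) p else p_adjusted) < alpha,
             row.names = NULL)
}

#' Two-sided paired t test
#'
#' Student t on the paired differences with `n - 1` degrees of freedom.
#' If every difference is exactly zero the test is vacuous and `t = 0`,
#' `p = 1` by convention; zero variance with a nonzero mean difference is
#' a degenerate input and raises an error.
#'
#' @param x,y Paired numeric samples of equal length >= 2.
#' @return A one-row data frame: `test`, `comparison`, `statistic`, `df`,
#'   `p_raw`, `p_adj` (`NA`), `significant`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  if (all(d == 0))
    return(stats_result("paired t", "x vs y", 0, length(d) - 1, 1))
  if (stats::var(d) == 0)
    stop("degenerate variance: identical nonzero differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  stats_result("paired t", "x vs y",
               unname(ht$statistic), unname(ht$parameter), ht$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in the raw
#' ordering.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' One-way analysis of variance
#'
#' F = between-group mean square / within-group mean square, with
#' `(k - 1, N - k)` degrees of freedom (equal-variance, fixed effects).
#'
#' @param groups List of numeric samples, each of length >= 2.
#' @return A one-row data frame as in [paired_t_test()]; `df` is the
#'   string `"df1,df2"` and `statistic` the F value.
#' @export
oneway_anova <- function(groups) {
  check_groups(groups)
  df <- groups_to_frame(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  ssb <- tab[["Sum Sq"]][1]; ssw <- tab[["Sum Sq"]][2]
  if (is.na(Fval) || ssb <= 1e-12 * (ssb + ssw)) {
    Fval <- 0; p <- 1                # identical group means (within round-off)
  }
  stats_result("one-way ANOVA", paste(names(groups), collapse = " | "),
               Fval, paste(tab[["Df"]], collapse = ","), p)
}

#' Tukey honest significant difference post-hoc test
#'
#' Pairwise group mean differences with studentized-range family-wise
#' p-values, following a one-way ANOVA fit.
#'
#' @inheritParams oneway_anova
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with one row per group pair: `comparison`,
#'   `difference`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_groups(groups)
  df <- groups_to_frame(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(comparison = rownames(tk),
                    difference = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    row.names = NULL)
  out$p_adj[is.na(out$p_adj)] <- 1                # zero within-group variance
  out$significant <- out$p_adj < alpha
  out
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group must contain at least two observations")
  invisible(groups)
}

groups_to_frame <- function(groups) {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  )
}

#' Layered diffusion-metric report with reference normalization
#'
#' For each timepoint (pre, post), lesion layer (core, boundary, outer)
#' and metric (ADC, AD, RD, MD, FA): the raw layer mean, the matching
#' timepoint's reference-region mean, and the normalized percentage.
#' Statistical comparisons:
#' \itemize{
#'   \item paired pre-vs-post t tests per (layer, metric) on per-voxel
#'     pairs within the layer mask, Benjamini-Hochberg corrected over the
#'     15-cell metric-by-layer family;
#'   \item per-timepoint one-way ANOVA across the three layers for each
#'     metric, with Tukey HSD post-hoc contrasts.
#' }
#' Voxel-level pairing treats each voxel of a layer as the paired unit;
#' with several subjects, subject-level summaries can be passed to
#' [paired_t_test()] directly instead.
#'
#' @param pre_maps,post_maps Named lists of scalar maps containing at
#'   least `ADC`, `AD`, `RD`, `MD`, `FA`, on a common grid.
#' @param layers A `lesion_layers` object from [make_layers()].
#' @param reference Logical mask of the reference region.
#' @param nested If `TRUE`, use the nested masks (core, full region,
#'   dilated region) instead of the default disjoint shells (core,
#'   boundary shell, outer shell).
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `layer_report`: list with `table`
#'   (per-cell means and normalized percentages), `paired` (FDR-corrected
#'   paired tests), `anova`, and `tukey` data frames.
#' @export
build_layer_report <- function(pre_maps, post_maps, layers, reference,
                               nested = FALSE, alpha = 0.05) {
  metrics <- c("ADC", "AD", "RD", "MD", "FA")
  missing_m <- setdiff(metrics, intersect(names(pre_maps), names(post_maps)))
  if (length(missing_m))
    stop("maps missing for metric(s): ", paste(missing_m, collapse = ", "))
  stopifnot(inherits(layers, "lesion_layers"))
  gs <- dim(layers$region)
  for (m in metrics)
    if (!all(dim(pre_maps[[m]]) == gs) || !all(dim(post_maps[[m]]) == gs))
      stop("map geometry does not match the layer masks")
  if (!all(dim(reference) == gs))
    stop("reference mask geometry does not match the layer masks")

  layer_masks <- if (nested)
    list(core = layers$core, boundary = layers$region,
         outer = layers$nested_outer)
  else
    list(core = layers$core, boundary = layers$boundary_shell,
         outer = layers$outer_shell)
  timepoints <- list(pre = pre_maps, post = post_maps)

  rows <- list()
  for (tp in names(timepoints)) {
    for (ly in names(layer_masks)) {
      for (m in metrics) {
        map <- timepoints[[tp]][[m]]
        raw <- roi_mean(map, layer_masks[[ly]])
        ref <- roi_mean(map, reference)
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint = tp, layer = ly, metric = m,
          raw_mean = raw, ref_mean = ref,
          normalized_pct = normalize_to_reference(raw, ref),
          n_voxels = sum(layer_masks[[ly]] & !is.na(map))
        )
      }
    }
  }
  table <- do.call(rbind, rows)

  paired <- list()
  for (ly in names(layer_masks)) {
    for (m in metrics) {
      sel <- layer_masks[[ly]] & !is.na(pre_maps[[m]]) & !is.na(post_maps[[m]])
      res <- paired_t_test(pre_maps[[m]][sel], post_maps[[m]][sel])
      res$comparison <- paste0(ly, ":", m, " pre vs post")
      paired[[length(paired) + 1L]] <- res
    }
  }
  paired <- do.call(rbind, paired)
  paired$p_adj <- fdr_adjust(paired$p_raw)
  paired$significant <- paired$p_adj < alpha

  anova <- list(); tukey <- list()
  for (tp in names(timepoints)) {
    for (m in metrics) {
      groups <- lapply(layer_masks, function(msk) {
        v <- timepoints[[tp]][[m]][msk]
        v[!is.na(v)]
      })
      a <- oneway_anova(groups)
      a$comparison <- paste0(tp, ":", m, " across layers")
      anova[[length(anova) + 1L]] <- a
      tk <- tukey_hsd(groups, alpha)
      tk <- cbind(timepoint = tp, metric = m, tk)
      tukey[[length(tukey) + 1L]] <- tk
    }
  }

  structure(list(table = table, paired = paired,
                 anova = do.call(rbind, anova),
                 tukey = do.call(rbind, tukey)),
            class = "layer_report")
}

#' @export
print.layer_report <- function(x, ...) {
  cat("<layer_report> ", nrow(x$table), " summary cells; ",
      sum(x$paired$significant), "/", nrow(x$paired),
      " paired tests significant (FDR)\n", sep = "")
  invisible(x)
}

#' Write a layer report as TSV files
#'
#' Writes `<prefix>_layers.tsv` (summary table) and `<prefix>_stats.tsv`
#' (paired tests, ANOVA, and Tukey contrasts stacked with a `test`
#' column).
#'
#' @param report A `layer_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_layer_report <- function(report, prefix) {
  stopifnot(inherits(report, "layer_report"))
  p1 <- paste0(prefix, "_layers.tsv")
  p2 <- paste0(prefix, "_stats.tsv")
  utils::write.table(report$table, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tk <- report$tukey
  stats_tab <- rbind(
    report$paired[, c("test", "comparison", "statistic", "df", "p_raw",
                      "p_adj", "significant")],
    report$anova[, c("test", "comparison", "statistic", "df", "p_raw",
                     "p_adj", "significant")],
    data.frame(test = "Tukey HSD",
               comparison = paste0(tk$timepoint, ":", tk$metric, " ",
                                   tk$comparison),
               statistic = tk$difference, df = NA,
               p_raw = NA, p_adj = tk$p_adj, significant = tk$significant)
  )
  utils::write.table(stats_tab, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
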