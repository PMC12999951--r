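REPLICON_CLASSES <- c("bacterial_chromosome", "archaeal_chromosome",
                      "bacterial_plasmid", "archaeal_plasmid", "other")

#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard estimator with the error contract the
#' pipeline relies on: inputs of unequal length, length < 3 or zero variance
#' raise an error rather than silently returning `NA` or 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance input")
  cor(x, y)
}

#' Per-replicon GSB-vs-CGC correlation set
#'
#' Computes the cumulative GSB curve and the five cumulative GC-skew curves
#' (total, codon positions 1-3, non-coding) on one common window grid and
#' returns the Pearson correlation of GSB against each. Correlations are taken
#' between the cumulative (plotted) curves. A class whose cumulative curve is
#' constant (e.g. no non-coding positions) yields `NA` for that entry, never
#' a silent 0.
#'
#' @param replicon a `replicon`.
#' @param features a `feature_table`.
#' @param window_size common window in bases (default 4096).
#' @param class_label replicon class for later aggregation.
#' @param gene_oriented passed to [windowed_skew()].
#' @param per_window correlate per-window skews instead of cumulative curves
#'   (sensitivity analysis).
#' @return object of class `correlation_set` with fields `replicon_id`,
#'   `class_label`, `pcc_total`, `pcc_codon1`, `pcc_codon2`, `pcc_codon3`,
#'   `pcc_noncoding`.
#' @export
replicon_correlation_set <- function(replicon, features, window_size = 4096L,
                                     class_label = "other",
                                     gene_oriented = FALSE,
                                     per_window = FALSE) {
  class_label <- match.arg(class_label, REPLICON_CLASSES)
  n_win <- replicon$length %/% window_size
  if (n_win < 3L) stop("need at least 3 complete windows, got ", n_win)
  labels <- build_position_labels(replicon, features)
  gsb <- gsb_profile(labels, window_size)$cumulative
  pccs <- vapply(SKEW_CLASSES, function(cl) {
    prof <- windowed_skew(replicon, labels, cl, window_size,
                          gene_oriented = gene_oriented)
    curve <- if (per_window) prof$values else cumsum(prof$values)
    if (var(curve) == 0 || var(gsb) == 0) return(NA_real_)
    pearson(gsb, curve)
  }, numeric(1))
  structure(list(replicon_id = replicon$id, class_label = class_label,
                 pcc_total = pccs[["total"]], pcc_codon1 = pccs[["codon1"]],
                 pcc_codon2 = pccs[["codon2"]], pcc_codon3 = pccs[["codon3"]],
                 pcc_noncoding = pccs[["noncoding"]]),
            class = "correlation_set")
}

#' Aggregate per-replicon correlations into a class summary
#'
#' The Table-1-shaped summary for one replicon class and one statistic:
#' mean, sample SD (n-1), coefficient of variation `100 * sd / |mean|`,
#' number of replicons, and the fraction with PCC > 0.5. `NA` entries are
#' dropped (with `n` reflecting the retained count). With a single value SD
#' and CV are reported as `NA`.
#'
#' @param sets list of `correlation_set`, all of one class.
#' @param statistic which entry to aggregate, e.g. `"pcc_total"`.
#' @return object of class `class_summary`: `class_label`, `statistic`,
#'   `mean`, `sd`, `cv_percent`, `n`, `frac_above_half`.
#' @export
aggregate_class <- function(sets, statistic = "pcc_total") {
  statistic <- match.arg(statistic, paste0("pcc_", SKEW_CLASSES))
  if (length(sets) == 0L) stop("empty correlation set list")
  cls <- unique(vapply(sets, `[[`, "", "class_label"))
  if (length(cls) != 1L)
    stop("aggregate_class expects a single class, got: ",
         paste(cls, collapse = ", "))
  v <- vapply(sets, `[[`, numeric(1), statistic)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no non-missing values for ", statistic)
  m <- mean(v)
  s <- if (length(v) > 1L) sd(v) else NA_real_
  structure(list(class_label = cls, statistic = statistic, mean = m, sd = s,
                 cv_percent = if (is.na(s)) NA_real_ else 100 * s / abs(m),
                 n = length(v), frac_above_half = mean(v > 0.5)),
            class = "class_summary")
}

#' Chargaff second-parity regression
#'
#' Counts G and C on the reference strand of each replicon and fits ordinary
#' least squares `C ~ G` across replicons; under the second parity rule the
#' slope is ~1 with r-squared ~1. Residuals are returned for inspection.
#'
#' @param replicons list of `replicon` (>= 2).
#' @return object of class `parity_fit`: `slope`, `intercept`, `r_squared`,
#'   `residuals`, `g_counts`, `c_counts`, `n`.
#' @export
chargaff_parity <- function(replicons) {
  if (length(replicons) < 2L) stop("need at least 2 replicons")
  g <- vapply(replicons, function(r) sum(base_codes(r) == 3L), numeric(1))
  c_ <- vapply(replicons, function(r) sum(base_codes(r) == 2L), numeric(1))
  if (var(g) == 0) stop("degenerate fit: all G counts identical")
  fit <- lm(c_ ~ g)
  r2 <- cor(g, c_)^2
  if (length(replicons) == 2L)
    message("parity fit on 2 replicons is exact by construction")
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]), r_squared = r2,
                 residuals = unname(fit$residuals), g_counts = g,
                 c_counts = c_, n = length(replicons)),
            class = "parity_fit")
}

#' Compare a statistic across replicon classes
#'
#' Two-group comparison with the two-tailed Mann-Whitney (Wilcoxon rank-sum)
#' test, or multi-group comparison with Kruskal-Wallis or one-way ANOVA.
#' Omnibus tests are followed by all-pairs post-hoc comparisons
#' (pairwise Wilcoxon or pairwise t-tests) with Holm adjustment.
#'
#' @param values_by_class named list mapping class label to a numeric vector
#'   (>= 2 groups, each of size >= 2).
#' @param method `"mann_whitney_two_tailed"`, `"kruskal_wallis"` or
#'   `"anova_oneway"`.
#' @return list with `method`, `statistic`, `p_value`, `groups` (n, mean,
#'   median per group) and, for omnibus methods, `pairwise` (Holm-adjusted
#'   p-value matrix).
#' @export
compare_groups <- function(values_by_class,
                           method = c("mann_whitney_two_tailed",
                                      "kruskal_wallis", "anova_oneway")) {
  method <- match.arg(method)
  if (length(values_by_class) < 2L) stop("need at least 2 groups")
  sizes <- vapply(values_by_class, length, 1L)
  if (any(sizes < 2L))
    stop("empty or singleton group: ",
         paste(names(values_by_class)[sizes < 2L], collapse = ", "))
  groups <- data.frame(
    class_label = names(values_by_class), n = sizes,
    mean = vapply(values_by_class, mean, numeric(1)),
    median = vapply(values_by_class, median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  value <- unlist(values_by_class, use.names = FALSE)
  label <- factor(rep(names(values_by_class), sizes))
  out <- list(method = method, groups = groups)
  if (method == "mann_whitney_two_tailed") {
    if (length(values_by_class) != 2L)
      stop("Mann-Whitney compares exactly 2 groups")
    ht <- suppressWarnings(wilcox.test(values_by_class[[1L]],
                                       values_by_class[[2L]],
                                       alternative = "two.sided"))
    out$statistic <- unname(ht$statistic); out$p_value <- ht$p.value
  } else if (method == "kruskal_wallis") {
    ht <- kruskal.test(value, label)
    out$statistic <- unname(ht$statistic); out$p_value <- ht$p.value
    out$pairwise <- suppressWarnings(
      pairwise.wilcox.test(value, label, p.adjust.method = "holm"))$p.value
  } else {
    fit <- aov(value ~ label)
    tab <- summary(fit)[[1L]]
    out$statistic <- tab[["F value"]][1L]; out$p_value <- tab[["Pr(>F)"]][1L]
    out$pairwise <- stats::pairwise.t.test(
      value, label, p.adjust.method = "holm")$p.value
  }
  out
}

#' Write class summaries as a Table-1-shaped TSV
#' @param summaries list of `class_summary`.
#' @param path output TSV.
#' @export
write_class_summary_tsv <- function(summaries, path) {
  if (inherits(summaries, "class_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(class_label = s$class_label, statistic = s$statistic,
               mean_pcc = s$mean, sd = s$sd, cv_percent = s$cv_percent,
               n = s$n, pct_above_half = 100 * s$frac_above_half,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
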