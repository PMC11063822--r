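#' Threshold-filter a differential-expression table
#'
#' Keeps rows with `padj <= padj_max` and `|log2fc| >= lfc_min` (both
#' boundaries inclusive) and labels them `"up"` or `"down"` by the sign of
#' the fold change. Rows with missing `padj` (not expressed under the
#' count-based model's criteria) are excluded. The operation is idempotent:
#' filtering an already-filtered table returns it unchanged.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `padj`.
#' @param lfc_min Minimum absolute log2 fold change (default 0.59).
#' @param padj_max Maximum adjusted p-value (default 0.05).
#' @return Tibble of the passing rows with an added `direction` column
#'   (`"up"`/`"down"`); attribute `n_excluded` counts the dropped rows.
#' @export
filter_de_table <- function(table, lfc_min = 0.59, padj_max = 0.05) {
  if (lfc_min <= 0 || padj_max <= 0) abort("thresholds must be positive")
  req <- c("gene", "log2fc", "padj")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0) {
    abort(paste0("table: missing column(s) ", paste(miss, collapse = ", ")))
  }
  tb <- as_tibble(table)
  keep <- !is.na(tb$padj) & tb$padj <= padj_max & abs(tb$log2fc) >= lfc_min
  out <- tb[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Top-k transcription factors by fold change
#'
#' Restricts a (filtered) DE table to genes on a supplied transcription-factor
#' membership list and returns the `k` strongest by descending `|log2fc|`,
#' ties broken by ascending `padj`, then by gene id.
#'
#' @param filtered A tibble from [filter_de_table()] (or any DE tibble with
#'   `gene`, `log2fc`, `padj`).
#' @param tf_genes Character vector of transcription-factor gene ids.
#' @param k Number of rows to return (default 20).
#' @return Tibble of at most `k` rows, ranked; fewer than `k` TFs triggers a
#'   message and returns them all.
#' @export
rank_top_tf <- function(filtered, tf_genes, k = 20) {
  tf <- dplyr::filter(as_tibble(filtered), .data$gene %in% tf_genes)
  tf <- dplyr::arrange(tf, desc(abs(.data$log2fc)), .data$padj, .data$gene)
  if (nrow(tf) < k) {
    inform(paste0("only ", nrow(tf), " transcription factors available (k = ",
                  k, "); returning all"))
  }
  utils::head(tf, k)
}

#' Normalize cell coordinates to the central canal and bounding box
#'
#' Maps section-pixel coordinates to `[-1, 1]^2` with the central canal at
#' the origin: positions on each side of the canal are scaled independently
#' by that side's extent (canal to bounding-box edge), so the right edge maps
#' to `x = +1`, the left edge to `x = -1`, and likewise dorso-ventrally
#' for `y`.
#'
#' @param coords Data frame with columns `x`, `y` (section pixels).
#' @param canal Numeric `(x, y)` of the central canal.
#' @param bbox Named list or vector with `left`, `right`, `dorsal`, `ventral`
#'   bounding-box extremes; must satisfy `left < canal x < right` and
#'   `dorsal < canal y < ventral` (strictly, no zero extents).
#' @return Tibble with added `x_norm`, `y_norm` columns.
#' @export
normalize_section_coords <- function(coords, canal, bbox) {
  bbox <- as.list(bbox)
  cx <- canal[[1]]; cy <- canal[[2]]
  if (bbox$right <= cx || cx <= bbox$left ||
      bbox$ventral <= cy || cy <= bbox$dorsal) {
    abort("bbox: canal must lie strictly inside the bounding box (no zero extents)")
  }
  scale_axis <- function(v, c, lo, hi) {
    ifelse(v >= c, (v - c) / (hi - c), (v - c) / (c - lo))
  }
  tb <- as_tibble(coords)
  tb$x_norm <- scale_axis(tb$x, cx, bbox$left, bbox$right)
  tb$y_norm <- scale_axis(tb$y, cy, bbox$dorsal, bbox$ventral)
  tb
}

#' @rdname normalize_section_coords
#' @param normalized A tibble with `x_norm`, `y_norm` columns.
#' @return For `denormalize_section_coords`, a tibble with recovered `x`,
#'   `y` columns.
#' @export
denormalize_section_coords <- function(normalized, canal, bbox) {
  bbox <- as.list(bbox)
  cx <- canal[[1]]; cy <- canal[[2]]
  unscale <- function(u, c, lo, hi) {
    ifelse(u >= 0, c + u * (hi - c), c + u * (c - lo))
  }
  tb <- as_tibble(normalized)
  tb$x <- unscale(tb$x_norm, cx, bbox$left, bbox$right)
  tb$y <- unscale(tb$y_norm, cy, bbox$dorsal, bbox$ventral)
  tb
}

#' Normality-gated group comparison
#'
#' Implements the test-selection tree used throughout the analyses: every
#' group is checked with the Shapiro-Wilk test; if all groups pass
#' (p > `shapiro_alpha`) a parametric test is used, otherwise a
#' nonparametric one. Two unpaired groups: Welch's t / Mann-Whitney U. Two
#' paired groups: paired t / Wilcoxon signed rank. Three or more groups:
#' Welch's one-way ANOVA / Kruskal-Wallis (unpaired), repeated-measures
#' ANOVA / Friedman (paired). The chosen test is always reported.
#'
#' @param data Data frame with columns `value`, `group` and (for paired
#'   designs) `subject`.
#' @param design `"unpaired"` or `"paired"`.
#' @param shapiro_alpha Significance gate of the normality check
#'   (default 0.05).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `all_normal`, `n_groups`.
#' @export
compare_groups <- function(data, design = c("unpaired", "paired"),
                           shapiro_alpha = 0.05) {
  design <- match.arg(design)
  tb <- as_tibble(data)
  if (!all(c("value", "group") %in% names(tb))) {
    abort("data: needs 'value' and 'group' columns")
  }
  tb$group <- factor(tb$group)
  groups <- split(tb$value, tb$group)
  k <- length(groups)
  if (k < 2) abort("data: need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 3)) abort("data: each group needs n >= 3")
  if (design == "paired") {
    if (!"subject" %in% names(tb)) abort("data: paired design needs 'subject'")
    if (length(unique(sizes)) != 1) {
      abort("data: paired design needs equal group sizes")
    }
    tb <- dplyr::arrange(tb, .data$group, .data$subject)
    groups <- split(tb$value, tb$group)
  }
  normal <- all(vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(FALSE)  # degenerate, treat as non-normal
    shapiro.test(g)$p.value > shapiro_alpha
  }, logical(1)))

  if (k == 2) {
    g1 <- groups[[1]]; g2 <- groups[[2]]
    if (design == "unpaired") {
      if (normal) {
        ht <- stats::t.test(g1, g2, var.equal = FALSE)
        res <- tibble(test = "Welch t", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value)
      } else {
        ht <- stats::wilcox.test(g1, g2, exact = FALSE)
        res <- tibble(test = "Mann-Whitney U", statistic = unname(ht$statistic),
                      df = NA_real_, p_value = ht$p.value)
      }
    } else {
      d <- g1 - g2
      if (all(d == 0)) {
        res <- tibble(test = if (normal) "paired t" else "Wilcoxon signed rank",
                      statistic = 0, df = length(d) - 1, p_value = 1)
      } else if (normal) {
        ht <- stats::t.test(g1, g2, paired = TRUE)
        res <- tibble(test = "paired t", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value)
      } else {
        ht <- stats::wilcox.test(g1, g2, paired = TRUE, exact = FALSE)
        res <- tibble(test = "Wilcoxon signed rank",
                      statistic = unname(ht$statistic),
                      df = NA_real_, p_value = ht$p.value)
      }
    }
  } else {
    if (design == "unpaired") {
      if (normal) {
        ht <- stats::oneway.test(value ~ group, data = tb, var.equal = FALSE)
        res <- tibble(test = "Welch ANOVA", statistic = unname(ht$statistic),
                      df = unname(ht$parameter[1]), p_value = ht$p.value)
      } else {
        ht <- stats::kruskal.test(value ~ group, data = tb)
        res <- tibble(test = "Kruskal-Wallis", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value)
      }
    } else {
      if (normal) {
        fit <- stats::aov(value ~ group + Error(factor(subject)), data = tb)
        sm <- summary(fit)
        tab <- sm[["Error: Within"]][[1]]
        res <- tibble(test = "repeated-measures ANOVA",
                      statistic = tab[["F value"]][1],
                      df = tab[["Df"]][1],
                      p_value = tab[["Pr(>F)"]][1])
      } else {
        ht <- stats::friedman.test(value ~ group | subject, data = tb)
        res <- tibble(test = "Friedman", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value)
      }
    }
  }
  dplyr::mutate(res, all_normal = normal, n_groups = k)
}
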