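#' Tissue concentration panel
#'
#' A panel of replicate internal concentrations grouped by tissue and
#' pigmentation line at a single sampling time. The statistical unit is the
#' pool (each replicate is one pool of 16 larval tissues), not the
#' individual larva.
#'
#' @param data A data.frame with columns `tissue`, `pigmentation`, `pool_id`,
#'   `conc_mg_per_kg`.
#' @return The validated data.frame with class `tissue_panel`.
#' @export
tissue_panel <- function(data) {
  required <- c("tissue", "pigmentation", "pool_id", "conc_mg_per_kg")
  missing <- setdiff(required, names(data))
  if (length(missing)) stop_invalid("missing panel columns: ", paste(missing, collapse = ", "))
  if (nrow(data) == 0L) stop_invalid("empty tissue panel")
  bad <- is.na(data$conc_mg_per_kg) | data$conc_mg_per_kg < 0
  if (any(bad)) {
    stop_invalid("negative or missing concentration at row(s) ",
                 paste(which(bad), collapse = ", "))
  }
  data <- data[, required, drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("tissue_panel", "data.frame")
  data
}

#' Summarise a panel: mean, SD and n per (tissue, pigmentation) group
#'
#' @param panel A [tissue_panel()].
#' @return A data.frame with columns `tissue`, `pigmentation`, `mean`, `sd`, `n`.
#' @export
panel_summary <- function(panel) {
  stopifnot(inherits(panel, "tissue_panel"))
  agg <- stats::aggregate(conc_mg_per_kg ~ tissue + pigmentation, data = panel,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- data.frame(tissue = agg$tissue, pigmentation = agg$pigmentation,
                    mean = agg$conc_mg_per_kg[, "mean"],
                    sd = agg$conc_mg_per_kg[, "sd"],
                    n = agg$conc_mg_per_kg[, "n"])
  out[order(out$tissue, out$pigmentation), , drop = FALSE]
}

#' One-way ANOVA with Tukey HSD across panel groups
#'
#' Compares concentrations across the panel's (tissue, pigmentation) groups
#' on the raw concentration scale (optionally log), with all-pairs Tukey HSD
#' adjusted p-values. Requires at least two groups with at least two pools
#' each; the significance threshold is reported alongside the p-values, not
#' baked into any decision.
#'
#' @param panel A [tissue_panel()].
#' @param log_scale Analyse log(concentration) instead of the raw scale.
#' @return A list of class `tissue_anova`: `f_statistic`, `p_value`,
#'   `pairwise` (data.frame with `pair`, `diff`, `p_unadjusted`, `p_adjusted`),
#'   `n_groups`, and the underlying `aov` object.
#' @export
tissue_anova <- function(panel, log_scale = FALSE) {
  stopifnot(inherits(panel, "tissue_panel"))
  d <- as.data.frame(panel)
  d$group <- factor(paste(d$tissue, d$pigmentation, sep = ":"))
  counts <- table(d$group)
  if (length(counts) < 2L) stop_invalid("ANOVA needs >= 2 groups (got ", length(counts), ")")
  if (any(counts < 2L)) {
    stop_invalid("ANOVA needs >= 2 replicate pools per group; short groups: ",
                 paste(names(counts)[counts < 2L], collapse = ", "))
  }
  d$y <- if (log_scale) log(d$conc_mg_per_kg) else d$conc_mg_per_kg
  fit <- stats::aov(y ~ group, data = d)
  an <- summary(fit)[[1L]]
  tuk <- stats::TukeyHSD(fit)$group
  pairs <- rownames(tuk)
  # unadjusted pairwise p from the same pooled-MSE model Tukey uses
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  p_unadj <- vapply(pairs, function(pr) {
    gs <- strsplit(pr, "-", fixed = TRUE)[[1L]]
    n1 <- sum(d$group == gs[1L]); n2 <- sum(d$group == gs[2L])
    diff <- mean(d$y[d$group == gs[1L]]) - mean(d$y[d$group == gs[2L]])
    tval <- diff / sqrt(mse * (1 / n1 + 1 / n2))
    2 * stats::pt(-abs(tval), fit$df.residual)
  }, numeric(1L))
  structure(
    list(
      f_statistic = an[["F value"]][1L],
      p_value = an[["Pr(>F)"]][1L],
      pairwise = data.frame(pair = pairs, diff = tuk[, "diff"],
                            p_unadjusted = unname(p_unadj),
                            p_adjusted = tuk[, "p adj"], row.names = NULL),
      n_groups = length(counts),
      aov = fit,
      scale = if (log_scale) "log" else "raw"
    ),
    class = "tissue_anova"
  )
}

#' @export
print.tissue_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s scale): F = %.4g, p = %.3g, %d groups\n",
              x$scale, x$f_statistic, x$p_value, x$n_groups))
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Pigmentation-line fold-reduction report
#'
#' For each tissue, the fold difference of the reference line's mean
#' concentration over each other line's mean, with Tukey-adjusted p-values
#' from a per-tissue one-way ANOVA across pigmentation lines (when
#' replication allows a test).
#'
#' @param panel A [tissue_panel()].
#' @param reference Reference pigmentation line; default `"WT"`.
#' @return A data.frame of class `pigmentation_report` with columns `tissue`,
#'   `pigmentation`, `mean`, `sd`, `n`, `fold_vs_reference`, `p_adjusted`.
#' @export
pigmentation_report <- function(panel, reference = "WT") {
  stopifnot(inherits(panel, "tissue_panel"))
  if (!reference %in% panel$pigmentation) {
    stop_invalid("reference pigmentation line \"", reference, "\" not present in panel")
  }
  summ <- panel_summary(panel)
  out <- NULL
  for (tis in unique(summ$tissue)) {
    s <- summ[summ$tissue == tis, , drop = FALSE]
    ref_mean <- s$mean[s$pigmentation == reference]
    if (length(ref_mean) == 0L) {
      stop_invalid("reference line \"", reference, "\" missing for tissue ", tis)
    }
    s$fold_vs_reference <- ref_mean / s$mean
    s$p_adjusted <- NA_real_
    sub <- panel[panel$tissue == tis, , drop = FALSE]
    can_test <- length(unique(sub$pigmentation)) >= 2L &&
      all(table(sub$pigmentation) >= 2L)
    if (can_test) {
      sub2 <- tissue_panel(as.data.frame(sub))
      av <- tissue_anova(sub2)
      for (i in seq_len(nrow(s))) {
        line <- s$pigmentation[i]
        if (line == reference) next
        g1 <- paste(tis, line, sep = ":"); g2 <- paste(tis, reference, sep = ":")
        hit <- av$pairwise$pair %in% paste(g1, g2, sep = "-") |
          av$pairwise$pair %in% paste(g2, g1, sep = "-")
        if (any(hit)) s$p_adjusted[i] <- av$pairwise$p_adjusted[hit][1L]
      }
    }
    out <- rbind(out, s)
  }
  rownames(out) <- NULL
  class(out) <- c("pigmentation_report", "data.frame")
  out
}
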