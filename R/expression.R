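#' RPKM of one gene in one library
#'
#' `RPKM = (1,000,000 * C * 1,000) / (N * L)` where `C` is the number of
#' reads uniquely aligned to the gene, `N` the total number of reads
#' uniquely aligned to all genes in the library, and `L` the gene length in
#' bases. No pseudo-counts: `C = 0` gives exactly 0.
#'
#' @param C Reads uniquely aligned to the gene (non-negative).
#' @param N Total uniquely aligned reads in the library (positive).
#' @param L Gene length in bases (positive).
#' @return RPKM value(s); vectorised over its arguments.
#' @export
compute_rpkm <- function(C, N, L) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(L < 1)) stop("L must be >= 1")
  if (any(C < 0)) stop("C must be non-negative")
  (1e6 * as.numeric(C) * 1e3) / (as.numeric(N) * as.numeric(L))
}

#' RPKM table and between-condition comparison
#'
#' Converts a count table to per-gene, per-condition RPKM, ranks genes by
#' abundance within each condition (ties broken by gene id) and, when a
#' numerator/denominator condition pair is given (default: the first two
#' conditions), reports their RPKM ratio. Ratios with a zero denominator are
#' reported as `Inf` (or `NaN` for 0/0) rather than through pseudo-counts.
#'
#' @param counts A `count_table` from [read_count_table()] or
#'   [make_count_table()].
#' @param numerator,denominator Condition names for the ratio; `NULL` uses
#'   the first two conditions (no ratio if only one condition).
#' @return List of class `rpkm_table`: `records` (gene_id, condition, C, N,
#'   L, rpkm, rank) and `comparison` (gene_id, ratio) or `NULL`.
#' @export
rpkm_table <- function(counts, numerator = NULL, denominator = NULL) {
  stopifnot(inherits(counts, "count_table"))
  tab <- counts$counts
  conds <- names(counts$lib_sizes)
  recs <- list()
  for (cc in conds) {
    rpkm <- compute_rpkm(tab[[cc]], counts$lib_sizes[[cc]], tab$length_bp)
    df <- data.frame(gene_id = tab$gene_id, condition = cc,
                     C = tab[[cc]], N = counts$lib_sizes[[cc]],
                     L = tab$length_bp, rpkm = rpkm,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$rpkm, df$gene_id), ]
    df$rank <- seq_len(nrow(df))
    recs[[cc]] <- df
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  comparison <- NULL
  if (is.null(numerator) && length(conds) >= 2L) {
    numerator <- conds[1L]
    denominator <- conds[2L]
  }
  if (!is.null(numerator)) {
    if (!all(c(numerator, denominator) %in% conds)) {
      stop("unknown condition in ratio request")
    }
    num <- compute_rpkm(tab[[numerator]], counts$lib_sizes[[numerator]],
                        tab$length_bp)
    den <- compute_rpkm(tab[[denominator]], counts$lib_sizes[[denominator]],
                        tab$length_bp)
    comparison <- data.frame(gene_id = tab$gene_id,
                             numerator = numerator, denominator = denominator,
                             ratio = num / den, stringsAsFactors = FALSE)
  }
  structure(list(records = records, comparison = comparison),
            class = "rpkm_table")
}

#' Fit a qPCR standard curve and compute amplification efficiency
#'
#' Ordinary least squares of Ct on log10 template amount. Efficiency in
#' percent is `100 * (10^(-1/slope) - 1)`; the assay passes when it lies in
#' the 90-110% window (a slope of -3.3219 corresponds to perfect doubling,
#' 100%).
#'
#' @param log10_amount Numeric vector of log10 template amounts.
#' @param ct Matching Ct values.
#' @param gene_id Optional identifier carried into the result.
#' @return List of class `efficiency_fit`: `gene_id`, `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`, `passes`.
#' @export
fit_standard_curve <- function(log10_amount, ct, gene_id = NA_character_) {
  if (length(log10_amount) != length(ct)) stop("length mismatch")
  if (length(unique(log10_amount)) < 3L) {
    stop("need at least 3 distinct dilution points")
  }
  fit <- stats::lm(ct ~ log10_amount)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff <- 100 * (10^(-1 / slope) - 1)
  passes <- is.finite(eff) && slope < 0 && eff >= 90 && eff <= 110
  if (slope >= 0) {
    warning("standard curve has non-negative slope; assay invalid")
  }
  structure(list(gene_id = gene_id, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency_percent = eff, passes = passes),
            class = "efficiency_fit")
}

#' Multi-reference relative quantification of qPCR data
#'
#' Technical replicates are averaged to one Ct per (gene, sample). Each
#' gene's relative quantity is `Q = E^(Ct_min - Ct)` with `Ct_min` the
#' minimal mean Ct of that gene across samples and `E` the gene's
#' amplification factor (default 2, i.e. 100% efficiency). The sample
#' normalization factor `NF` is the geometric mean of the reference genes'
#' `Q` in that sample; normalized expression is `Q / NF`, which cancels any
#' sample-loading shift affecting references and targets equally. When a
#' calibrator sample is given, fold changes are relative to it.
#'
#' @param ct A `ct_table` (long format, technical replicates as rows).
#' @param reference_genes Character vector of reference gene ids (each must
#'   be measured in every sample).
#' @param efficiencies Named numeric vector of per-gene amplification
#'   factors (e.g. 2 for 100% efficiency); genes absent from it default to
#'   2.
#' @param calibrator Sample id used as fold-change baseline, or `NULL`.
#' @return Data frame: `gene_id`, `sample_id`, `group_label`, `ct_mean`,
#'   `Q`, `NF`, `norm`, and `fold` when a calibrator is given.
#' @export
vandesompele_normalize <- function(ct, reference_genes, efficiencies = NULL,
                                   calibrator = NULL) {
  stopifnot(is.data.frame(ct))
  if (length(reference_genes) < 1L) stop("need at least one reference gene")
  if (!is.null(efficiencies) && any(efficiencies <= 0)) {
    stop("amplification factors must be positive")
  }
  agg <- stats::aggregate(ct ~ gene_id + sample_id + group_label,
                          data = as.data.frame(ct), FUN = mean)
  names(agg)[names(agg) == "ct"] <- "ct_mean"
  samples <- unique(agg$sample_id)
  for (rg in reference_genes) {
    present <- agg$sample_id[agg$gene_id == rg]
    missing <- setdiff(samples, present)
    if (length(missing) > 0L) {
      stop("reference gene ", rg, " missing in sample ", missing[1L])
    }
  }
  eff_of <- function(g) {
    e <- if (!is.null(efficiencies) && g %in% names(efficiencies)) {
      efficiencies[[g]]
    } else 2
    e
  }
  agg$Q <- NA_real_
  for (g in unique(agg$gene_id)) {
    idx <- agg$gene_id == g
    ctm <- agg$ct_mean[idx]
    agg$Q[idx] <- eff_of(g)^(min(ctm) - ctm)
  }
  nf <- vapply(samples, function(s) {
    geometric_mean(vapply(reference_genes, function(rg) {
      agg$Q[agg$gene_id == rg & agg$sample_id == s]
    }, 0))
  }, 0)
  names(nf) <- samples
  agg$NF <- nf[agg$sample_id]
  agg$norm <- agg$Q / agg$NF
  if (!is.null(calibrator)) {
    if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
    base <- agg$norm[agg$sample_id == calibrator]
    names(base) <- agg$gene_id[agg$sample_id == calibrator]
    agg$fold <- agg$norm / base[agg$gene_id]
  }
  agg[order(agg$gene_id, agg$sample_id), ]
}

#' One-way ANOVA with LSD compact letter display
#'
#' Classical one-way ANOVA followed by Fisher's least significant
#' difference: groups `i`, `j` differ iff
#' `|mean_i - mean_j| > t(1 - alpha/2, df_error) * sqrt(MSE (1/n_i + 1/n_j))`.
#' Letters come from insert-and-absorb over groups sorted by descending
#' mean, so groups that are not significantly different share at least one
#' letter. With zero within-group variance, unequal means are reported with
#' `F = Inf` and letters follow the exact ordering; all-identical groups
#' give `F = 0` and a single shared letter.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), one per value; at least
#'   two groups with at least two replicates each.
#' @param alpha Significance level for the LSD comparisons.
#' @return List of class `anova_letters`: `means`, `n`, `F`, `p`, `mse`,
#'   `df_error`, `letters` (named by group), `different` (logical matrix).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n <- table(groups)
  if (any(n < 2L)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(n)[n < 2L], collapse = ", "))
  }
  means <- tapply(values, groups, mean)
  within_ss <- sum((values - means[groups])^2)
  fit <- stats::aov(values ~ groups)
  atab <- suppressWarnings(stats::anova(fit))
  mse <- atab[["Mean Sq"]][2L]
  df_error <- atab[["Df"]][2L]
  degenerate <- within_ss <= 1e-12 * max(1, sum(values^2))
  if (degenerate) mse <- 0
  if (!degenerate) {
    Fval <- atab[["F value"]][1L]
    pval <- atab[["Pr(>F)"]][1L]
  } else if (max(means) - min(means) > 0) {
    Fval <- Inf
    pval <- 0
  } else {
    Fval <- 0
    pval <- 1
  }
  tcrit <- stats::qt(1 - alpha / 2, df_error)
  lev <- levels(groups)
  k <- length(lev)
  diffmat <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      lsd <- tcrit * sqrt(mse * (1 / n[[i]] + 1 / n[[j]]))
      sig <- abs(means[[i]] - means[[j]]) > lsd
      diffmat[i, j] <- diffmat[j, i] <- sig
    }
  }
  letters <- .cld_insert_absorb(means, diffmat)
  structure(list(means = means, n = as.vector(n), F = Fval, p = pval,
                 mse = mse, df_error = df_error, letters = letters,
                 different = diffmat),
            class = "anova_letters")
}

# Compact letter display by insert-and-absorb: start from one class holding
# every group; for each significantly different pair split every class
# containing both; drop classes that are subsets of others; assign letters
# to classes ordered by the largest mean they contain.
.cld_insert_absorb <- function(means, diffmat) {
  lev <- names(means)
  ord <- lev[order(-unlist(means), lev)]
  classes <- list(ord)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i < j && diffmat[ord[i], ord[j]]) {
        nxt <- list()
        for (cl in classes) {
          if (all(c(ord[i], ord[j]) %in% cl)) {
            nxt <- c(nxt, list(setdiff(cl, ord[i])), list(setdiff(cl, ord[j])))
          } else {
            nxt <- c(nxt, list(cl))
          }
        }
        # absorb: drop duplicates and classes contained in a larger class
        nxt <- unique(lapply(nxt, sort))
        keep <- rep(TRUE, length(nxt))
        for (a in seq_along(nxt)) {
          for (b in seq_along(nxt)) {
            if (a != b && keep[b] && length(nxt[[a]]) < length(nxt[[b]]) &&
                all(nxt[[a]] %in% nxt[[b]])) {
              keep[a] <- FALSE
            }
          }
        }
        classes <- nxt[keep]
      }
    }
  }
  # order classes by the best mean they contain; letter them a, b, c, ...
  best <- vapply(classes, function(cl) max(unlist(means)[cl]), 0)
  classes <- classes[order(-best)]
  lab <- stats::setNames(rep("", length(lev)), lev)
  for (ci in seq_along(classes)) {
    for (g in classes[[ci]]) {
      lab[g] <- paste0(lab[g], letters[ci])
    }
  }
  lab
}
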