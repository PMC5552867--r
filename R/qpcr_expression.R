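#' Construct / validate a Ct table
#'
#' Long-format qPCR results: one row per (sample, gene) with the cycle
#' threshold and that primer pair's amplification efficiency. Every sample
#' must carry a Ct for the reference gene. Undetectable transcripts are
#' represented as `NA` Ct (censored), never zero-filled.
#'
#' @param df A `data.frame` with columns `sample_id`, `treatment`, `gene`,
#'   `ct`, `efficiency`.
#' @param ref_gene Reference (internal control) gene name.
#' @return The validated `data.frame` of class `ct_table`.
#' @export
ct_table <- function(df, ref_gene) {
  need <- c("sample_id", "treatment", "gene", "ct", "efficiency")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  if (!ref_gene %in% df$gene)
    stop("ref_gene absent from table", call. = FALSE)
  if (any(df$efficiency <= 1 | df$efficiency > 2, na.rm = TRUE))
    stop("efficiencies must lie in (1, 2]", call. = FALSE)
  if (any(df$ct <= 0, na.rm = TRUE))
    stop("ct values must be positive", call. = FALSE)
  ref <- df[df$gene == ref_gene, ]
  missing_ref <- setdiff(unique(df$sample_id),
                         ref$sample_id[!is.na(ref$ct)])
  if (length(missing_ref))
    stop("samples without a reference-gene ct: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  attr(df, "ref_gene") <- ref_gene
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Amplification efficiency from a dilution standard curve
#'
#' OLS of Ct against log10 input amount over a serial dilution;
#' `E = 10^(-1/slope)` (E = 2 for the ideal -3.32 cycles/decade slope).
#'
#' @param dilution_log10 log10 of relative input amounts (>= 3 points, not
#'   all equal).
#' @param ct Measured Ct at each dilution.
#' @return A list: `efficiency` (fold per cycle), `percent` ((E-1)*100),
#'   `slope`, `r_squared`.
#' @examples
#' efficiency_from_standard_curve(0:-3 , 20 + 3.9 * (0:3)) # E ~ 1.805
#' @export
efficiency_from_standard_curve <- function(dilution_log10, ct) {
  stopifnot(is.numeric(dilution_log10), is.numeric(ct),
            length(dilution_log10) == length(ct))
  if (length(unique(dilution_log10)) < 3L)
    stop("need >= 3 distinct dilution points", call. = FALSE)
  fit <- stats::lm(ct ~ dilution_log10)
  m <- unname(stats::coef(fit)[2L])
  if (m >= 0)
    stop("ct must decrease with input amount (negative slope)",
         call. = FALSE)
  e <- 10^(-1 / m)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ct - mean(ct))^2)
  list(efficiency = e, percent = (e - 1) * 100, slope = m, r_squared = r2)
}

# Ct of one gene in one sample (NA when censored/absent).
.ct_of <- function(tab, gene, sample) {
  v <- tab$ct[tab$gene == gene & tab$sample_id == sample]
  if (length(v) == 0L) NA_real_ else v[1L]
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Efficiency-corrected delta-delta-Ct fold change
#'
#' Relative expression of `gene` in each sample against the control-group
#' mean, normalized to the reference gene. The default (`method =
#' "efficiency"`) is the Pfaffl-style ratio using each primer pair's own
#' efficiency,
#' `E_gene^(ct_ctrl_mean - ct_sample) / E_ref^(refct_ctrl_mean - refct_sample)`,
#' which reduces to the classic `2^-ddct` when all efficiencies are 2
#' (`method = "classic"` forces E = 2).
#'
#' @param table A [ct_table()].
#' @param gene Target gene.
#' @param control_group,treated_group Treatment labels (defaults
#'   `"normoxia"`, `"hypoxia"`).
#' @param method `"efficiency"` (default) or `"classic"`.
#' @return A list: `per_sample` data.frame (`sample_id`, `treatment`,
#'   `fold`), `mean_fold`/`sem_fold` per group, `excluded` sample ids,
#'   `gene`, `method`.
#' @export
ddct_fold_change <- function(table, gene,
                             control_group = "normoxia",
                             treated_group = "hypoxia",
                             method = c("efficiency", "classic")) {
  stopifnot(inherits(table, "ct_table"))
  method <- match.arg(method)
  ref_gene <- attr(table, "ref_gene")
  if (!gene %in% table$gene) stop("gene absent from table", call. = FALSE)
  e_gene <- table$efficiency[table$gene == gene][1L]
  e_ref <- table$efficiency[table$gene == ref_gene][1L]
  if (method == "classic") e_gene <- e_ref <- 2
  groups <- c(control_group, treated_group)
  sub <- table[table$treatment %in% groups, , drop = FALSE]
  samples <- unique(sub[, c("sample_id", "treatment")])
  ct_g <- vapply(samples$sample_id, function(s) .ct_of(sub, gene, s),
                 numeric(1))
  ct_r <- vapply(samples$sample_id, function(s) .ct_of(sub, ref_gene, s),
                 numeric(1))
  ok <- !is.na(ct_g) & !is.na(ct_r)
  excluded <- samples$sample_id[!ok]
  if (length(excluded))
    message("ddct_fold_change: excluding samples without ct: ",
            paste(excluded, collapse = ", "))
  samples <- samples[ok, , drop = FALSE]
  ct_g <- ct_g[ok]; ct_r <- ct_r[ok]
  ctrl <- samples$treatment == control_group
  if (!any(ctrl)) stop("no control samples with usable ct", call. = FALSE)
  fold <- e_gene^(mean(ct_g[ctrl]) - ct_g) / e_ref^(mean(ct_r[ctrl]) - ct_r)
  per <- data.frame(sample_id = samples$sample_id,
                    treatment = samples$treatment, fold = fold)
  summ <- lapply(split(per$fold, per$treatment), function(v)
    c(mean = mean(v), sem = .sem(v), n = length(v)))
  list(per_sample = per,
       mean_fold = vapply(summ, `[[`, numeric(1), "mean"),
       sem_fold = vapply(summ, `[[`, numeric(1), "sem"),
       excluded = excluded, gene = gene, ref_gene = ref_gene,
       method = method)
}

#' Anchored within-sample relative transcript abundance
#'
#' Relative amount of each gene within a sample, against an anchor gene
#' (the predominant isoform), with proper incorporation of per-primer
#' efficiencies: `abundance_n = E_anchor^ct_anchor / E_n^ct_n`. The anchor's
#' own abundance is 1 in every sample by construction. Genes with censored
#' (NA) Ct get NA abundance; samples without an anchor Ct are excluded.
#'
#' @param table A [ct_table()].
#' @param anchor_gene Anchor gene name.
#' @param genes Genes to report (default: all but the reference gene).
#' @return A list: `per_sample` data.frame (`sample_id`, `treatment`,
#'   `gene`, `abundance`), `group_summary` data.frame (`treatment`, `gene`,
#'   `mean`, `sem`, `percent`), `anchor_gene`.
#' @export
relative_abundance <- function(table, anchor_gene, genes = NULL) {
  stopifnot(inherits(table, "ct_table"))
  ref_gene <- attr(table, "ref_gene")
  if (!anchor_gene %in% table$gene)
    stop("anchor gene absent from table", call. = FALSE)
  if (is.null(genes)) genes <- setdiff(unique(table$gene), ref_gene)
  eff <- vapply(c(anchor_gene, genes), function(g)
    table$efficiency[table$gene == g][1L], numeric(1))
  samples <- unique(table[, c("sample_id", "treatment")])
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample_id[i]
    ct_a <- .ct_of(table, anchor_gene, s)
    if (is.na(ct_a)) next  # anchor undetected: sample excluded
    for (g in genes) {
      ct_n <- .ct_of(table, g, s)
      ab <- if (is.na(ct_n)) NA_real_ else
        eff[[anchor_gene]]^ct_a / eff[[g]]^ct_n
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, treatment = samples$treatment[i], gene = g,
        abundance = ab)
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per, list(per$treatment, per$gene), drop = TRUE),
    function(d) {
      v <- d$abundance[!is.na(d$abundance)]
      data.frame(treatment = d$treatment[1L], gene = d$gene[1L],
                 mean = mean(v), sem = .sem(v),
                 percent = 100 * mean(v), n = length(v))
    }))
  rownames(agg) <- NULL
  list(per_sample = per, group_summary = agg, anchor_gene = anchor_gene)
}
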