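#' Read an SGA colony table (TSV)
#'
#' Columns: `gene`, `plate`, optionally `position` and `set_label`, and one
#' or more `exp_<i>` / `ctrl_<i>` colony-size columns.
#'
#' @param path Path to the TSV.
#' @return An `SGATable` data frame.
#' @export
read_sga_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "plate") %in% names(tab)))
    stop("SGA table needs 'gene' and 'plate' columns")
  if (!any(grepl("^exp_", names(tab))) || !any(grepl("^ctrl_", names(tab))))
    stop("SGA table needs exp_<i> and ctrl_<i> colony-size columns")
  if (!"set_label" %in% names(tab)) tab$set_label <- "none"
  class(tab) <- c("SGATable", "data.frame")
  tab
}

#' Write an SGA colony table (TSV)
#'
#' @param table An `SGATable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sga_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative growth per deletion strain
#'
#' Plate-median spatial normalization followed by the condition ratio: each
#' colony size is divided by the median size on its plate (per condition
#' and replicate), then
#' `relative_growth = median(normalized exp) / median(normalized ctrl)`.
#' Strains whose control median is 0 cannot be scored and come back `NA`
#' (flagged for exclusion from tests).
#'
#' @param table An `SGATable` with `exp_<i>`/`ctrl_<i>` columns.
#' @return Numeric vector of per-strain relative growth (NA where control
#'   is missing/zero), named by gene.
#' @export
relative_growth <- function(table) {
  exp_cols <- grep("^exp_", names(table), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(table), value = TRUE)
  if (length(exp_cols) == 0 || length(ctrl_cols) == 0)
    stop("need at least one replicate per condition")
  norm_block <- function(cols) {
    vapply(cols, function(cl) {
      x <- table[[cl]]
      med <- stats::ave(x, table$plate,
                        FUN = function(v) stats::median(v, na.rm = TRUE))
      x / med
    }, numeric(nrow(table)))
  }
  ne <- norm_block(exp_cols)
  nc <- norm_block(ctrl_cols)
  me <- apply(ne, 1, stats::median, na.rm = TRUE)
  mc <- apply(nc, 1, stats::median, na.rm = TRUE)
  rg <- ifelse(is.na(mc) | mc <= 0, NA_real_, me / mc)
  names(rg) <- table$gene
  rg
}

#' Classify strains into rescuers / sensitizers / neutral
#'
#' `rescuer` if relative growth exceeds `pos_threshold` (the deletion
#' relieves toxicity), `sensitizer` below `neg_threshold`, else `neutral`.
#' With `NULL` thresholds, `1 +/- 2 * robust SD` is used, where the robust
#' SD is `1.4826 * MAD` of the finite relative-growth values.
#'
#' @param rg Per-strain relative growth (from [relative_growth()]).
#' @param pos_threshold,neg_threshold Growth thresholds; `NULL` derives
#'   them from the data.
#' @return Factor with levels `sensitizer`, `neutral`, `rescuer` (NA rg
#'   stays NA); thresholds attached as attribute `thresholds`.
#' @export
classify_hits <- function(rg, pos_threshold = NULL, neg_threshold = NULL) {
  if (is.null(pos_threshold) || is.null(neg_threshold)) {
    s <- 1.4826 * stats::mad(rg[is.finite(rg)], center = 1, constant = 1)
    if (is.null(pos_threshold)) pos_threshold <- 1 + 2 * s
    if (is.null(neg_threshold)) neg_threshold <- 1 - 2 * s
  }
  if (neg_threshold >= pos_threshold)
    stop("neg_threshold must be < pos_threshold")
  cls <- ifelse(rg > pos_threshold, "rescuer",
                ifelse(rg < neg_threshold, "sensitizer", "neutral"))
  cls <- factor(cls, levels = c("sensitizer", "neutral", "rescuer"))
  attr(cls, "thresholds") <- c(neg = neg_threshold, pos = pos_threshold)
  cls
}

# chi-squared statistic for an observed table against expected counts
chisq_stat <- function(obs, expd) sum((obs - expd)^2 / expd)

#' Gene-set chi-squared tests for the SGA screen
#'
#' Two null hypotheses about the histone gene sets:
#' \describe{
#'   \item{H01}{gene deletions that affect histone levels (any set member)
#'     are distributed across the rescuer/neutral/sensitizer classes as all
#'     strains are: chi-squared on the 2 x 3 (in-set vs not) x class
#'     table.}
#'   \item{H02}{deletions that increase vs decrease histone levels fall
#'     below vs above the growth thresholds by chance: chi-squared on the
#'     2 x 2 (histone_up vs histone_down) x (sensitizer vs rescuer) table
#'     of non-neutral set members.}
#' }
#' No continuity correction is applied; when any expected cell count falls
#' below 5 a Fisher exact test replaces the chi-squared p with a warning.
#'
#' @param classes Factor from [classify_hits()].
#' @param set_label Per-strain set membership (`"histone_up"`,
#'   `"histone_down"`, or `"none"`).
#' @param up_label,down_label Names of the two polarized sets.
#' @return A list with `p_H01`, `p_H02`, the statistics/df, and both
#'   contingency tables.
#' @export
chi2_geneset_tests <- function(classes, set_label,
                               up_label = "histone_up",
                               down_label = "histone_down") {
  ok <- !is.na(classes)
  classes <- classes[ok]
  set_label <- set_label[ok]
  in_set <- set_label %in% c(up_label, down_label)
  if (!any(in_set)) stop("no strains in the histone sets")

  # H01: 2 x 3 in-set vs class
  t1 <- table(factor(in_set, levels = c(FALSE, TRUE)), classes,
              dnn = c("in_set", "class"))
  chi1 <- chisq_or_exact(t1)

  # H02: 2 x 2 polarity vs threshold side, non-neutral set members only
  sel <- in_set & classes != "neutral"
  if (sum(sel) == 0) stop("no non-neutral strains in the histone sets")
  polarity <- factor(set_label[sel], levels = c(up_label, down_label))
  side <- factor(as.character(classes[sel]),
                 levels = c("sensitizer", "rescuer"))
  t2 <- table(polarity, side)
  chi2 <- chisq_or_exact(t2)

  list(p_H01 = chi1$p, p_H02 = chi2$p,
       stat_H01 = chi1$stat, df_H01 = chi1$df,
       stat_H02 = chi2$stat, df_H02 = chi2$df,
       method_H01 = chi1$method, method_H02 = chi2$method,
       table_H01 = t1, table_H02 = t2)
}

# Pearson chi-squared (no continuity correction) with Fisher fallback when
# expected counts are small.
chisq_or_exact <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate contingency table: test not computable")
    return(list(p = NA_real_, stat = NA_real_, df = NA_real_,
                method = "degenerate"))
  }
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (any(expd < 5)) {
    warning("expected cell count < 5: using Fisher's exact test")
    p <- stats::fisher.test(tab)$p.value
    return(list(p = p, stat = NA_real_, df = df, method = "fisher"))
  }
  stat <- chisq_stat(as.numeric(tab), as.numeric(expd))
  list(p = stats::pchisq(stat, df, lower.tail = FALSE),
       stat = stat, df = df, method = "chisq")
}

#' Hypergeometric gene-category enrichment
#'
#' Upper-tail hypergeometric test per functional category: the probability
#' of drawing at least the observed number of category members when
#' `length(rescuers)` genes are sampled from the universe without
#' replacement. Bonferroni-adjusted p-values are reported alongside raw
#' ones. Categories with no members in the universe are skipped with a
#' warning.
#'
#' @param rescuers Character vector of hit genes (e.g. rescuer deletions).
#' @param categories Named list of gene sets (category -> genes).
#' @param universe All screened genes.
#' @return Data frame: `category`, `hits`, `category_size`, `n_drawn`,
#'   `universe`, `p`, `p_bonferroni`, sorted by `p`.
#' @export
category_enrichment <- function(rescuers, categories, universe) {
  rescuers <- intersect(rescuers, universe)
  n <- length(rescuers)
  N <- length(universe)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], universe)
    if (length(cat_genes) == 0) {
      warning(sprintf("category '%s' disjoint from universe: skipped", nm))
      return(NULL)
    }
    K <- length(cat_genes)
    k <- length(intersect(rescuers, cat_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, hits = k, category_size = K, n_drawn = n,
               universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable categories")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}

#' Full SGA screen stage
#'
#' Chains [relative_growth()], [classify_hits()], [chi2_geneset_tests()]
#' and (when categories are supplied) [category_enrichment()].
#'
#' @param table An `SGATable` (with a `set_label` column).
#' @param pos_threshold,neg_threshold Growth thresholds (NULL = robust
#'   defaults).
#' @param categories Optional named list of category gene sets.
#' @return A list with `relative_growth`, `classes`, `thresholds`,
#'   `tests`, and `enrichment` (NULL if no categories).
#' @export
sga_stage <- function(table, pos_threshold = NULL, neg_threshold = NULL,
                      categories = NULL) {
  rg <- relative_growth(table)
  cls <- classify_hits(rg, pos_threshold, neg_threshold)
  tests <- chi2_geneset_tests(cls, table$set_label)
  enr <- NULL
  if (!is.null(categories)) {
    rescuers <- table$gene[!is.na(cls) & cls == "rescuer"]
    enr <- category_enrichment(rescuers, categories, table$gene)
  }
  list(relative_growth = rg, classes = cls,
       thresholds = attr(cls, "thresholds"),
       tests = tests, enrichment = enr)
}
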