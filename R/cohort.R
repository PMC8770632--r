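#' Classify cell lines as wild-type or mutant for a gene
#'
#' A cell line is called mutant when it carries at least one non-silent,
#' non-deleterious mutation in the gene - the pattern of typically
#' activating (e.g. hotspot) variants. Silent and deleterious (loss of
#' function) variants do not count; cell lines absent from the mutation
#' table are wild-type.
#'
#' @param mutations Data frame with columns `cell_line`, `gene`,
#'   `is_silent`, `is_deleterious`, `is_hotspot` (logical flags).
#' @param gene Gene symbol to classify by.
#' @param cell_lines Character vector of the full cohort.
#' @return Named factor over `cell_lines`, levels `c("wt", "mut")`.
#' @export
classify_mutation_status <- function(mutations, gene, cell_lines) {
  gene <- normalize_symbol(gene)
  rec <- mutations[normalize_symbol(mutations$gene) == gene &
                     !mutations$is_silent & !mutations$is_deleterious, ,
                   drop = FALSE]
  status <- ifelse(cell_lines %in% rec$cell_line, "mut", "wt")
  stats::setNames(factor(status, levels = c("wt", "mut")), cell_lines)
}

#' Classify a dependency probability as dependent or independent
#'
#' Dependent means the probability of membership in the essential-gene
#' score distribution strictly exceeds the threshold ("over 50%" at the
#' default).
#'
#' @param prob Numeric vector of dependency probabilities in [0, 1].
#' @param threshold Classification threshold; default 0.5.
#' @return Factor with levels `c("independent", "dependent")`, names kept.
#' @export
classify_dependent <- function(prob, threshold = 0.5) {
  if (any(is.na(prob)) || any(prob < 0 | prob > 1)) {
    stop("dependency probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- factor(ifelse(prob > threshold, "dependent", "independent"),
                levels = c("independent", "dependent"))
  names(out) <- names(prob)
  out
}

#' Relative copy number of a gene within one sample
#'
#' The gene's copy number divided by the arithmetic mean copy number over
#' all genes of the same sample (NA entries excluded from the mean).
#'
#' @param cn_row Named numeric vector: copy number per gene for one cell
#'   line, linear scale.
#' @param gene Gene symbol.
#' @return A single number.
#' @export
relative_copy_number <- function(cn_row, gene) {
  gene <- normalize_symbol(gene)
  if (!gene %in% normalize_symbol(names(cn_row))) {
    stop("gene ", gene, " absent from copy-number profile", call. = FALSE)
  }
  m <- mean(cn_row, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("mean copy number must be positive", call. = FALSE)
  }
  unname(cn_row[normalize_symbol(names(cn_row)) == gene][1L]) / m
}

#' Flag amplification from relative copy number
#'
#' Amplified when the relative copy number strictly exceeds the threshold.
#'
#' @param rel_cn Numeric vector of relative copy numbers (>= 0).
#' @param threshold Amplification threshold; default 3.
#' @return Logical vector, names kept.
#' @export
classify_amplified <- function(rel_cn, threshold = 3) {
  stats::setNames(rel_cn > threshold, names(rel_cn))
}

#' Build the binary RAS-activating-event (RAE) marker matrix
#'
#' One binary column per dependency marker gene (dependent at > 0.5
#' probability) plus a final amplification column. A cell line "has an
#' RAE" when any marker is set.
#'
#' @param dep_prob Cell line x gene matrix of dependency probabilities.
#' @param marker_genes Marker gene symbols (must be columns of `dep_prob`).
#' @param amplified Named logical vector over the same cell lines.
#' @param threshold Dependency threshold; default 0.5.
#' @return Integer matrix (cell line x marker) with attribute `has_rae`,
#'   a named logical vector.
#' @export
build_rae_matrix <- function(dep_prob, marker_genes, amplified,
                             threshold = 0.5) {
  marker_genes <- normalize_symbol(marker_genes)
  missing <- setdiff(marker_genes, colnames(dep_prob))
  if (length(missing) > 0L) {
    stop("marker gene(s) absent from dependency matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- rownames(dep_prob)
  m <- (dep_prob[, marker_genes, drop = FALSE] > threshold) * 1L
  amp <- as.integer(amplified[cells])
  out <- cbind(m, amplification = amp)
  attr(out, "has_rae") <- stats::setNames(rowSums(out) > 0, cells)
  out
}

#' Encode per-cell-line mutation-status predictors
#'
#' Three binary indicators per cell line for the target gene, following
#' the three-category encoding of mutation data: `deleterious` (any
#' deleterious variant), `hotspot` and `other` (both restricted to
#' non-silent, non-deleterious variants, split by the hotspot annotation).
#' All three are 0 when the line has no qualifying mutation.
#'
#' @inheritParams classify_mutation_status
#' @return Integer matrix (cell line x 3), columns `deleterious`,
#'   `hotspot`, `other`.
#' @export
encode_mutation_predictors <- function(mutations, gene, cell_lines) {
  gene <- normalize_symbol(gene)
  rec <- mutations[normalize_symbol(mutations$gene) == gene, , drop = FALSE]
  activating <- rec[!rec$is_silent & !rec$is_deleterious, , drop = FALSE]
  out <- cbind(
    deleterious = as.integer(cell_lines %in%
                               rec$cell_line[rec$is_deleterious]),
    hotspot = as.integer(cell_lines %in%
                           activating$cell_line[activating$is_hotspot]),
    other = as.integer(cell_lines %in%
                         activating$cell_line[!activating$is_hotspot]))
  rownames(out) <- cell_lines
  out
}

#' Compare dependency between two cell-line groups
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test. The exact distribution
#' is used for combined sample sizes up to 20 when there are no ties;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used. The choice is reported in the result.
#'
#' @param values_a,values_b Numeric vectors (both nonempty).
#' @return List with `statistic` (the rank-sum W for the first group),
#'   `p_value`, and `method` (`"exact"` or `"normal_approximation"`).
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- (length(values_a) + length(values_b)) <= 20L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic),
       p_value = res$p.value,
       method = if (exact) "exact" else "normal_approximation")
}
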