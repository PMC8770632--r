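#' Read a STRING-style protein interaction edge list
#'
#' Parses an edge-list file in the STRING links dialect: a header naming the
#' two protein columns (`protein1`, `protein2`) and a confidence column
#' (`combined_score`), separated by whitespace or tabs. The score scale is
#' detected automatically: integer scores above 1 are taken to be on the
#' STRING 0-1000 scale, otherwise scores are assumed to lie in [0, 1].
#'
#' Rows with a non-numeric or negative score are rejected with a warning
#' naming the offending row numbers; the remaining rows are kept.
#'
#' @param path Path to the edge-list file.
#' @param dialect Input dialect; only `"string_tsv"` is supported.
#' @return A data frame with columns `protein_a`, `protein_b`, `score` and
#'   attribute `score_scale` (`"0-1000"` or `"0-1"`).
#' @export
read_interactions <- function(path, dialect = "string_tsv") {
  dialect <- match.arg(dialect, "string_tsv")
  if (!file.exists(path)) {
    stop("interaction file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           check.names = FALSE)
  cols <- tolower(names(raw))
  p1 <- match(TRUE, cols %in% c("protein1", "protein_a", "protein_1"))
  p2 <- match(TRUE, cols %in% c("protein2", "protein_b", "protein_2"))
  sc <- match(TRUE, cols %in% c("combined_score", "score", "weight"))
  if (is.na(p1) || is.na(p2) || is.na(sc)) {
    stop("edge list must contain columns 'protein1', 'protein2' and ",
         "'combined_score' (got: ", paste(names(raw), collapse = ", "), ")",
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("edge list contains a header but no interactions", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(raw[[sc]]))
  bad <- which(is.na(score) | score < 0)
  if (length(bad) > 0L) {
    warning("rejected ", length(bad), " malformed interaction row(s): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ..." else "", call. = FALSE)
    raw <- raw[-bad, , drop = FALSE]
    score <- score[-bad]
  }
  if (nrow(raw) == 0L) {
    stop("no valid interaction rows after removing malformed entries",
         call. = FALSE)
  }
  out <- data.frame(protein_a = raw[[p1]], protein_b = raw[[p2]],
                    score = score, stringsAsFactors = FALSE)
  attr(out, "score_scale") <- if (max(score) > 1) "0-1000" else "0-1"
  out
}

#' Read a STRING-style protein-to-gene alias table
#'
#' Expects the STRING aliases dialect: columns `protein`, `alias` and
#' optionally `source`. When a protein has several aliases, the first listed
#' is used. Gene symbols are whitespace-trimmed and uppercased.
#'
#' @param path Path to the alias file.
#' @return A named character vector mapping protein identifier to gene symbol.
#' @export
read_aliases <- function(path) {
  if (!file.exists(path)) {
    stop("alias file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(names(raw))
  pc <- match(TRUE, cols %in% c("protein", "protein_id", "string_protein_id"))
  ac <- match(TRUE, cols %in% c("alias", "gene", "symbol", "preferred_name"))
  if (is.na(pc) || is.na(ac)) {
    stop("alias table must contain columns 'protein' and 'alias'",
         call. = FALSE)
  }
  keep <- !duplicated(raw[[pc]])
  stats::setNames(normalize_symbol(raw[[ac]][keep]),
                  as.character(raw[[pc]][keep]))
}

#' Map protein interactions to gene level and merge duplicates
#'
#' Protein pairs are translated to unordered gene pairs through the alias
#' map; interactions involving an unmapped protein are dropped (counted in
#' the `n_unmapped` attribute). Scores of duplicated gene pairs are replaced
#' by their arithmetic mean, and self-loops (both proteins mapping to the
#' same gene) are removed.
#'
#' @param interactions Data frame from [read_interactions()].
#' @param aliases Named character vector from [read_aliases()].
#' @return A data frame with columns `gene_a`, `gene_b`, `score`
#'   (`gene_a < gene_b` lexicographically), carrying attributes
#'   `score_scale`, `n_unmapped` and `n_self_loops`.
#' @export
map_and_merge <- function(interactions, aliases) {
  if (length(aliases) == 0L) {
    stop("alias map is empty", call. = FALSE)
  }
  ga <- unname(aliases[interactions$protein_a])
  gb <- unname(aliases[interactions$protein_b])
  unmapped <- is.na(ga) | is.na(gb)
  n_unmapped <- sum(unmapped)
  ga <- ga[!unmapped]
  gb <- gb[!unmapped]
  score <- interactions$score[!unmapped]
  self <- ga == gb
  n_self <- sum(self)
  ga <- ga[!self]; gb <- gb[!self]; score <- score[!self]
  if (length(score) == 0L) {
    stop("no mappable gene-level interactions remain", call. = FALSE)
  }
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  key <- paste(lo, hi, sep = "\r")
  mean_score <- tapply(score, key, mean)
  keys <- sort(names(mean_score))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                    gene_b = vapply(parts, `[[`, "", 2L),
                    score = unname(mean_score[keys]),
                    stringsAsFactors = FALSE)
  attr(out, "score_scale") <- attr(interactions, "score_scale") %||%
    (if (max(out$score) > 1) "0-1000" else "0-1")
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_self_loops") <- n_self
  out
}

#' Discard low-confidence edges below a score percentile
#'
#' Computes the given percentile of the score distribution over all input
#' edges (linear interpolation between order statistics) and retains edges
#' whose score is greater than or equal to that threshold, so edges tied
#' with the threshold survive.
#'
#' @param edges Gene-level edge data frame from [map_and_merge()].
#' @param percentile Percentile in (0, 100); default 90.
#' @return The filtered edge data frame with attribute `score_threshold`.
#' @export
threshold_edges <- function(edges, percentile = 90) {
  if (nrow(edges) == 0L) {
    stop("edge list is empty", call. = FALSE)
  }
  thr <- percentile_threshold(edges$score, percentile)
  out <- edges[edges$score >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "score_scale") <- attr(edges, "score_scale")
  attr(out, "score_threshold") <- thr
  attr(out, "score_percentile") <- percentile
  out
}

#' Restrict a gene-level network to the shells around a focal gene
#'
#' Keeps the focal gene (shell 0), its direct interaction partners
#' (shell 1), and, for `shells = 2`, partners of shell-1 genes (shell 2).
#' Edges are retained only if both endpoints survive. Shell labels are the
#' unweighted breadth-first distances from the focal gene. Edge weights are
#' rescaled to [0, 1] when the input is on the STRING 0-1000 scale.
#'
#' @param edges Gene-level edge data frame (typically from
#'   [threshold_edges()]).
#' @param focal Focal gene symbol.
#' @param shells Maximum shell to retain (1 or 2; default 2).
#' @return An object of class `interaction_network`: a list with elements
#'   `genes` (lexicographic), `edges` (data frame `gene_a`, `gene_b`,
#'   `weight` in (0, 1]), `focal_gene`, `shell` (named integer vector) and
#'   `provenance`.
#' @export
shell_restrict <- function(edges, focal, shells = 2) {
  focal <- normalize_symbol(focal)
  if (!shells %in% c(1L, 2L)) {
    stop("`shells` must be 1 or 2", call. = FALSE)
  }
  scale <- attr(edges, "score_scale") %||%
    (if (nrow(edges) > 0 && max(edges$score) > 1) "0-1000" else "0-1")
  touching <- edges$gene_a == focal | edges$gene_b == focal
  if (!any(touching)) {
    warning("focal gene ", focal,
            " has no incident edges; returning a single-node network",
            call. = FALSE)
    return(new_interaction_network(
      genes = focal,
      edges = data.frame(gene_a = character(), gene_b = character(),
                         weight = numeric(), stringsAsFactors = FALSE),
      focal_gene = focal,
      shell = stats::setNames(0L, focal),
      provenance = list(score_threshold = attr(edges, "score_threshold"),
                        shells = shells, n_input_edges = nrow(edges))))
  }
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  dist <- igraph::distances(g, v = focal)[1L, ]
  keep_genes <- names(dist)[dist <= shells]
  shell <- stats::setNames(as.integer(dist[keep_genes]), keep_genes)
  keep_edges <- edges$gene_a %in% keep_genes & edges$gene_b %in% keep_genes
  e <- edges[keep_edges, , drop = FALSE]
  w <- if (identical(scale, "0-1000")) e$score / 1000 else e$score
  genes <- sort(keep_genes)
  ord <- order(e$gene_a, e$gene_b)
  new_interaction_network(
    genes = genes,
    edges = data.frame(gene_a = e$gene_a[ord], gene_b = e$gene_b[ord],
                       weight = w[ord], stringsAsFactors = FALSE),
    focal_gene = focal,
    shell = shell[genes],
    provenance = list(score_threshold = attr(edges, "score_threshold"),
                      score_percentile = attr(edges, "score_percentile"),
                      shells = shells, n_input_edges = nrow(edges)))
}

new_interaction_network <- function(genes, edges, focal_gene, shell,
                                    provenance = list()) {
  structure(list(genes = genes, edges = edges, focal_gene = focal_gene,
                 shell = shell, provenance = provenance),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network around", x$focal_gene, "\n")
  cat("  genes:", length(x$genes),
      sprintf("(shell 1: %d, shell 2: %d)",
              sum(x$shell == 1L), sum(x$shell == 2L)), "\n")
  cat("  edges:", nrow(x$edges), "\n")
  if (!is.null(x$provenance$score_threshold)) {
    cat("  score threshold:", format(x$provenance$score_threshold), "\n")
  }
  invisible(x)
}

#' Build a focal-gene network from STRING-style input files
#'
#' Convenience wrapper running the full network-construction pipeline:
#' read interactions and aliases, map to gene level (averaging duplicate
#' pairs, dropping self-loops and unmapped proteins), discard edges below
#' the score percentile, and restrict to the focal gene's shells.
#'
#' @param edge_file STRING links-dialect file.
#' @param alias_file STRING aliases-dialect file.
#' @param focal Focal gene symbol (e.g. `"KRAS"`).
#' @param score_percentile Edge-score percentile filter; default 90.
#' @param shells Maximum shell; default 2.
#' @return An `interaction_network` object.
#' @export
build_network <- function(edge_file, alias_file, focal,
                          score_percentile = 90, shells = 2) {
  inter <- read_interactions(edge_file)
  aliases <- read_aliases(alias_file)
  merged <- map_and_merge(inter, aliases)
  filt <- threshold_edges(merged, score_percentile)
  shell_restrict(filt, focal, shells)
}

#' Write a network as an edge-list TSV with a JSON sidecar
#'
#' @param network An `interaction_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "network_edges.tsv")
  meta_path <- file.path(dir, "network_meta.json")
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(focal_gene = network$focal_gene,
               n_genes = length(network$genes),
               n_edges = nrow(network$edges),
               shell_counts = as.list(table(network$shell)),
               provenance = network$provenance)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(edges = edge_path, meta = meta_path))
}
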