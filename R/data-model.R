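#' EWAS results container
#'
#' Holds per-CpG association results from an epigenome-wide association study
#' (EWAS): one ranking metric per CpG, plus how that metric ranks CpGs. The
#' metric may be a p-value, a test statistic, or a variable-importance score;
#' ranking direction defaults to smaller-is-better for p-values and
#' larger-is-better otherwise.
#'
#' @param cpg character vector of CpG identifiers (unique).
#' @param metric numeric ranking metric, one per CpG; p-values must lie in
#'   (0, 1].
#' @param metric_kind one of `"pvalue"`, `"statistic"`, `"importance"`.
#' @param rank_direction `"smaller_better"` or `"larger_better"`; defaults by
#'   `metric_kind`. P-values must use `"smaller_better"`.
#' @return An object of class `ewas_results`: a list with elements `data`
#'   (data.frame with columns `cpg`, `metric`), `metric_kind`,
#'   `rank_direction`.
#' @export
ewas_results <- function(cpg, metric,
                         metric_kind = c("pvalue", "statistic", "importance"),
                         rank_direction = NULL) {
  metric_kind <- match.arg(metric_kind)
  if (is.null(rank_direction)) {
    rank_direction <- if (metric_kind == "pvalue") "smaller_better" else "larger_better"
  }
  rank_direction <- match.arg(rank_direction, c("smaller_better", "larger_better"))
  cpg <- as.character(cpg)
  if (length(cpg) != length(metric)) stopf("cpg and metric lengths differ")
  if (length(cpg) == 0L) stopf("EWAS results are empty")
  if (anyNA(cpg) || any(cpg == "")) stopf("missing/empty cpg identifiers")
  if (!is.numeric(metric) || anyNA(metric)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(metric))))[1]
    if (is.na(bad)) bad <- 1L
    stopf("non-numeric or missing metric at row %d (cpg '%s')", bad, cpg[bad])
  }
  dup <- cpg[duplicated(cpg)]
  if (length(dup)) stopf("duplicate cpg identifier(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (metric_kind == "pvalue") {
    if (rank_direction != "smaller_better")
      stopf("p-value metrics must use rank_direction = 'smaller_better'")
    bad <- which(metric <= 0 | metric > 1)
    if (length(bad)) stopf("p-value outside (0,1] at row %d (cpg '%s', value %g)",
                           bad[1], cpg[bad[1]], metric[bad[1]])
  }
  structure(list(data = data.frame(cpg = cpg, metric = as.numeric(metric),
                                   stringsAsFactors = FALSE),
                 metric_kind = metric_kind, rank_direction = rank_direction),
            class = "ewas_results")
}

#' Read EWAS results from a TSV file
#'
#' Expects a tab-separated file with header columns `cpg` and `metric`.
#'
#' @inheritParams ewas_results
#' @param path path to the TSV file.
#' @return An [ewas_results] object.
#' @export
read_ewas <- function(path, metric_kind = c("pvalue", "statistic", "importance"),
                      rank_direction = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("cpg", "metric"), names(tab))
  if (length(miss)) stopf("EWAS file '%s' lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (!is.numeric(tab$metric)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$metric))))[1]
    stopf("non-numeric metric at row %d of '%s'", bad %||% 1L, path)
  }
  ewas_results(tab$cpg, tab$metric, metric_kind, rank_direction)
}

#' Default gene-identifier normalizer
#'
#' Trims surrounding whitespace and upper-cases identifiers so that trivially
#' different spellings of the same symbol collapse. Identifiers are otherwise
#' treated as opaque strings: they only need to match between the eQTM
#' resource and the pathway database.
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @export
normalize_gene_id <- function(x) toupper(trimws(as.character(x)))

#' Create a validated eQTM resource
#'
#' An eQTM (expression quantitative trait methylation) resource is a table of
#' empirical CpG-to-gene links: effect size (e.g. correlation), distance from
#' the CpG to the gene's transcription start site, and the pair's association
#' p-value. Many-to-many links are allowed. Gene identifiers are normalized,
#' exact duplicate (cpg, gene) pairs are collapsed keeping the row with the
#' largest absolute effect, and per-gene unique-CpG counts c(g) are derived.
#'
#' @param table data.frame with columns `cpg`, `gene`, `effect`, `distance`,
#'   `pair_pvalue`.
#' @param id_normalizer function applied to gene identifiers
#'   (default [normalize_gene_id]).
#' @return Object of class `eqtm`: list with `pairs` (validated data.frame)
#'   and `gene_counts` (named integer vector c(g), unique CpGs per gene).
#' @export
create_eqtm <- function(table, id_normalizer = normalize_gene_id) {
  if (inherits(table, "eqtm")) table <- table$pairs
  need <- c("cpg", "gene", "effect", "distance", "pair_pvalue")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("eQTM table lacks column(s): %s", paste(miss, collapse = ", "))
  cpg <- as.character(table$cpg)
  gene <- id_normalizer(table$gene)
  effect <- as.numeric(table$effect)
  distance <- as.numeric(table$distance)
  pp <- as.numeric(table$pair_pvalue)
  if (nrow(table) == 0L) stopf("eQTM table is empty")
  if (anyNA(cpg) || any(cpg == "")) stopf("missing cpg identifier in eQTM table")
  bad <- which(is.na(gene) | gene == "")
  if (length(bad)) stopf("empty gene identifier after normalization at row %d", bad[1])
  bad <- which(!is.finite(effect))
  if (length(bad)) stopf("missing/non-finite effect at row %d", bad[1])
  bad <- which(!is.finite(distance) | distance < 0)
  if (length(bad)) stopf("negative or missing distance at row %d (value %s)",
                         bad[1], format(distance[bad[1]]))
  bad <- which(!is.finite(pp) | pp <= 0 | pp > 1)
  if (length(bad)) stopf("pair_pvalue outside (0,1] at row %d", bad[1])

  # collapse duplicate (cpg, gene) pairs, keeping the strongest evidence
  ord <- order(cpg, gene, -abs(effect))
  df <- data.frame(cpg = cpg, gene = gene, effect = effect, distance = distance,
                   pair_pvalue = pp, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  keep <- !duplicated(df[c("cpg", "gene")])
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL

  counts <- tapply(df$cpg, df$gene, function(x) length(unique(x)))
  gene_counts <- as.integer(counts)
  names(gene_counts) <- names(counts)
  structure(list(pairs = df, gene_counts = gene_counts), class = "eqtm")
}

#' Read an eQTM resource from a TSV file
#'
#' Expects header columns `cpg`, `gene`, `effect`, `distance`, `pair_pvalue`.
#' Signed upstream/downstream distances are absolute-valued on read; the
#' resource stores non-negative distance magnitudes.
#'
#' @inheritParams create_eqtm
#' @param path path to the TSV file.
#' @return An `eqtm` object, see [create_eqtm()].
#' @export
read_eqtm <- function(path, id_normalizer = normalize_gene_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("distance" %in% names(tab)) tab$distance <- abs(as.numeric(tab$distance))
  create_eqtm(tab, id_normalizer)
}

#' @export
print.eqtm <- function(x, ...) {
  cat(sprintf("eQTM resource: %d CpG-gene pairs, %d CpGs, %d genes\n",
              nrow(x$pairs), length(unique(x$pairs$cpg)), length(x$gene_counts)))
  invisible(x)
}

#' Construct a pathway database
#'
#' @param genesets named list of character vectors (gene identifiers per
#'   pathway); names are pathway ids, all sets non-empty.
#' @param pathway_names optional named character vector of display names
#'   (defaults to the ids).
#' @param hierarchy optional data.frame with columns `parent`, `child` giving
#'   parent-to-child pathway edges; must reference known pathways and be
#'   acyclic.
#' @param top_level optional character vector of top-level pathway ids;
#'   defaults to hierarchy parents that never appear as a child.
#' @param id_normalizer function applied to member gene identifiers.
#' @return Object of class `pathway_db`: list with `genesets`, `pathway_names`,
#'   `hierarchy`, `top_level`.
#' @export
pathway_db <- function(genesets, pathway_names = NULL, hierarchy = NULL,
                       top_level = NULL, id_normalizer = normalize_gene_id) {
  if (!length(genesets)) stopf("pathway database is empty")
  ids <- names(genesets)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stopf("pathway gene sets must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate pathway name(s): %s",
                         paste(unique(dup), collapse = ", "))
  genesets <- lapply(genesets, function(g) unique(id_normalizer(g)))
  empty <- ids[vapply(genesets, length, 0L) == 0L]
  if (length(empty)) stopf("empty gene set(s): %s", paste(empty, collapse = ", "))
  if (is.null(pathway_names)) pathway_names <- stats::setNames(ids, ids)
  if (!is.null(hierarchy)) {
    hierarchy <- data.frame(parent = as.character(hierarchy$parent),
                            child = as.character(hierarchy$child),
                            stringsAsFactors = FALSE)
    unknown <- setdiff(c(hierarchy$parent, hierarchy$child), ids)
    if (length(unknown)) stopf("hierarchy references unknown pathway(s): %s",
                               paste(unknown, collapse = ", "))
    if (has_cycle(hierarchy)) stopf("pathway hierarchy contains a cycle")
    if (is.null(top_level))
      top_level <- sort(setdiff(unique(hierarchy$parent), hierarchy$child))
  }
  if (!is.null(top_level)) {
    unknown <- setdiff(top_level, ids)
    if (length(unknown)) stopf("top_level references unknown pathway(s): %s",
                               paste(unknown, collapse = ", "))
  }
  structure(list(genesets = genesets, pathway_names = pathway_names,
                 hierarchy = hierarchy, top_level = top_level),
            class = "pathway_db")
}

# Kahn-style leaf stripping on parent->child edges
has_cycle <- function(edges) {
  e <- unique(edges[c("parent", "child")])
  while (nrow(e)) {
    leaves <- setdiff(e$child, e$parent)
    if (!length(leaves)) return(TRUE)
    e <- e[!(e$child %in% leaves), , drop = FALSE]
  }
  FALSE
}

#' Read a GMT gene-set file
#'
#' One pathway per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate pathway names and empty gene lists are rejected.
#'
#' @param path path to the GMT file.
#' @param id_normalizer function applied to member gene identifiers.
#' @return A [pathway_db] object (without hierarchy).
#' @export
read_gmt <- function(path, id_normalizer = normalize_gene_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L)) stopf("GMT line %d has fewer than 3 fields", which(nf < 3L)[1])
  ids <- vapply(fields, `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate pathway name(s) in GMT: %s",
                         paste(unique(dup), collapse = ", "))
  descs <- vapply(fields, `[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- ids
  pathway_db(sets, pathway_names = stats::setNames(descs, ids),
             id_normalizer = id_normalizer)
}

#' Read a pathway hierarchy table and attach it to a database
#'
#' @param path TSV file with header columns `parent`, `child`.
#' @return data.frame with columns `parent`, `child`.
#' @export
read_hierarchy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("parent", "child"), names(tab))
  if (length(miss)) stopf("hierarchy file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab[c("parent", "child")]
}

#' @rdname read_hierarchy
#' @param db a [pathway_db] object.
#' @param hierarchy data.frame with columns `parent`, `child`.
#' @param top_level optional character vector of top-level pathway ids.
#' @export
set_hierarchy <- function(db, hierarchy, top_level = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  pathway_db(db$genesets, db$pathway_names, hierarchy = hierarchy,
             top_level = top_level, id_normalizer = identity)
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d genes%s\n", length(x$genesets),
              length(unique(unlist(x$genesets, use.names = FALSE))),
              if (is.null(x$hierarchy)) "" else
                sprintf(", %d hierarchy edges, %d top-level",
                        nrow(x$hierarchy), length(x$top_level))))
  invisible(x)
}

#' Read a CpG-to-nearest-gene annotation
#'
#' Classical-baseline annotation: exactly one gene per CpG, TSV with header
#' columns `cpg`, `gene`.
#'
#' @param path path to the TSV file.
#' @param id_normalizer function applied to gene identifiers.
#' @return named character vector mapping cpg id to gene id.
#' @export
read_annotation <- function(path, id_normalizer = normalize_gene_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("cpg", "gene"), names(tab))
  if (length(miss)) stopf("annotation file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  cpg <- as.character(tab$cpg)
  dup <- cpg[duplicated(cpg)]
  if (length(dup)) stopf("annotation maps cpg(s) to multiple genes: %s",
                         paste(unique(dup), collapse = ", "))
  gene <- id_normalizer(tab$gene)
  if (any(gene == "" | is.na(gene))) stopf("empty gene in annotation")
  stats::setNames(gene, cpg)
}

vote_table_columns <- c("pathway_id", "name", "votes", "hmp", "calibrated_p",
                        "q_bh", "n_union_genes", "union_genes")

#' Write / read a vote table
#'
#' The vote table is written as TSV sorted by `q_bh`, then `hmp`, then
#' `pathway_id` (a total, documented order so identical runs are
#' byte-identical). Columns: pathway_id, name, votes, hmp, calibrated_p, q_bh,
#' n_union_genes, union_genes (semicolon-joined).
#'
#' @param vt a vote table as returned by [aggregate_votes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_vote_table <- function(vt, path) {
  df <- as.data.frame(vt)[, vote_table_columns, drop = FALSE]
  if (nrow(df)) {
    df <- df[order(df$q_bh, df$hmp, df$pathway_id), , drop = FALSE]
    for (col in c("hmp", "calibrated_p", "q_bh"))
      df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vote_table
#' @export
read_vote_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(pathway_id = "character", name = "character",
                                         union_genes = "character"))
  df$union_genes[is.na(df$union_genes)] <- ""
  class(df) <- c("vote_table", "data.frame")
  df
}
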