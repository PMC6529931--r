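# Gene regulatory enhancer network (GREN): deduplication and numbering of
# classified enhancers, differential selections, graph assembly, and
# extraction of the disease-specific subnetwork.

#' Merge duplicate enhancers across conditions and map promoters to genes
#'
#' Overlapping enhancer intervals from the classified pair list are merged
#' into single regions; a merged region is classed `CH` when called pairs from
#' both conditions land on it, otherwise `C` or `H`. Pairs are re-pointed at
#' the merged regions and promoters are mapped to gene symbols via
#' `gene_map`; pairs whose promoter has no mapping are dropped with the count
#' reported. Multiple promoters of one gene collapse onto the gene symbol.
#'
#' @param pairs Classified pair tibble from [call_and_classify()] (`gene`,
#'   `chrom`, `e_start`, `e_end`, `condition`, `class`).
#' @param gene_map Optional named character vector promoter-gene -> symbol;
#'   `NULL` keeps the `gene` column as the symbol.
#' @return List with `enhancers` (merged regions with `class` and
#'   `enhancer_id` placeholder) and `pairs` (remapped, one row per
#'   enhancer-gene link per condition).
#' @export
dedup_enhancers <- function(pairs, gene_map = NULL) {
  stopifnot(all(c("gene", "chrom", "e_start", "e_end", "condition", "class")
                %in% names(pairs)))
  if (!is.null(gene_map)) {
    mapped <- unname(gene_map[pairs$gene])
    dropped <- sum(is.na(mapped))
    if (dropped > 0) {
      message(dropped, " pair(s) dropped: promoter without gene mapping")
    }
    pairs$gene <- mapped
    pairs <- pairs[!is.na(pairs$gene), ]
  }
  if (nrow(pairs) == 0) {
    return(list(enhancers = tibble(chrom = character(), start = integer(),
                                   end = integer(), class = character()),
                pairs = pairs))
  }
  enh <- tibble(chrom = pairs$chrom, start = pairs$e_start,
                end = pairs$e_end)
  merged <- merge_intervals(enh)
  hits <- interval_hits(enh, merged)
  stopifnot(nrow(hits) == nrow(enh))  # every enhancer maps to one merged region
  pairs$region <- hits$y_idx[order(hits$x_idx)]
  cls <- pairs |>
    group_by(.data$region) |>
    summarise(
      class = {
        conds <- unique(.data$condition[.data$class %in% c("C", "H", "CH")])
        both <- all(c("CLL", "NBC") %in% conds) | any(.data$class == "CH")
        if (both) "CH" else if ("CLL" %in% conds) "C" else "H"
      },
      .groups = "drop"
    )
  merged$class <- "H"
  merged$class[cls$region] <- cls$class
  pairs_out <- pairs |>
    mutate(e_start = merged$start[.data$region],
           e_end = merged$end[.data$region]) |>
    distinct(.data$gene, .data$chrom, .data$e_start, .data$e_end,
             .data$condition, .keep_all = TRUE) |>
    select(-"region")
  list(enhancers = merged, pairs = pairs_out)
}

#' Number enhancers consecutively within class
#'
#' Assigns ids `C1, C2, ...`, `H1, ...`, `CH1, ...` in genomic order (chrom,
#' start) within each class, starting at 1. Input row order does not affect
#' the assignment.
#'
#' @param enhancers Merged enhancer tibble with a `class` column.
#' @return `enhancers` sorted genomically with an `enhancer_id` column.
#' @export
number_enhancers <- function(enhancers) {
  stopifnot("class" %in% names(enhancers))
  enhancers |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$class) |>
    mutate(enhancer_id = paste0(.data$class, dplyr::row_number())) |>
    ungroup()
}

#' Select differentially active regulators
#'
#' Regulators with Benjamini-Hochberg adjusted P below `alpha` (strict `<`).
#' If the table lacks an adjusted column, BH adjustment is applied to `p`.
#'
#' @param tbl Tibble with `regulator`, `p`, and optionally `padj`.
#' @param alpha Adjusted-P threshold.
#' @return Character vector of selected regulators.
#' @export
select_differential_regulators <- function(tbl, alpha = 0.05) {
  stopifnot(all(c("regulator", "p") %in% names(tbl)))
  if (!"padj" %in% names(tbl)) {
    tbl$padj <- stats::p.adjust(tbl$p, method = "BH")
  }
  tbl$regulator[tbl$padj < alpha]
}

#' Select deregulated non-regulator genes
#'
#' Genes with `p < alpha` (0.01) and `|LFC| > min_abs_lfc` (1.7), both strict.
#'
#' @param tbl Tibble with `gene`, `p`, `lfc`.
#' @param alpha P-value threshold (strict `<`).
#' @param min_abs_lfc Absolute log fold-change threshold (strict `>`).
#' @return Character vector of selected genes.
#' @export
select_deregulated_genes <- function(tbl, alpha = 0.01, min_abs_lfc = 1.7) {
  stopifnot(all(c("gene", "p", "lfc") %in% names(tbl)))
  tbl$gene[tbl$p < alpha & abs(tbl$lfc) > min_abs_lfc]
}

#' Assemble the gene regulatory enhancer network
#'
#' Integrates enhancer-gene interactions into a regulator-target network:
#' nodes are regulators, target genes, and numbered enhancers; directed
#' regulator-to-gene edges come from the input network and undirected
#' enhancer-gene edges from the remapped pairs. Genes in `modifier_list` are
#' flagged as chromatin modifiers. Enhancer-gene edges to genes absent from
#' the network are dropped with the count reported.
#'
#' @param grn_edges Tibble with `regulator` and `target` gene symbols.
#' @param enhancers Numbered enhancer tibble from [number_enhancers()].
#' @param pairs Remapped pair tibble from [dedup_enhancers()].
#' @param modifier_list Character vector of chromatin-modifier gene symbols.
#' @return A `gren` object: list with `nodes` (name, type, is_modifier, class,
#'   chrom, start, end) and `edges` (from, to, kind) tibbles.
#' @export
assemble_gren <- function(grn_edges, enhancers = NULL, pairs = NULL,
                          modifier_list = character()) {
  stopifnot(all(c("regulator", "target") %in% names(grn_edges)))
  regulators <- unique(grn_edges$regulator)
  targets <- setdiff(unique(grn_edges$target), regulators)
  genes <- union(regulators, targets)
  nodes <- tibble(
    name = c(regulators, targets),
    type = c(rep("regulator", length(regulators)),
             rep("target_gene", length(targets))),
    is_modifier = c(regulators, targets) %in% modifier_list,
    class = NA_character_, chrom = NA_character_,
    start = NA_integer_, end = NA_integer_
  )
  edges <- tibble(from = grn_edges$regulator, to = grn_edges$target,
                  kind = "regulates")
  if (!is.null(pairs) && nrow(pairs) > 0) {
    stopifnot(!is.null(enhancers), "enhancer_id" %in% names(enhancers))
    key <- paste(enhancers$chrom, enhancers$start, enhancers$end)
    pid <- enhancers$enhancer_id[
      match(paste(pairs$chrom, pairs$e_start, pairs$e_end), key)]
    stopifnot(!any(is.na(pid)))
    links <- distinct(tibble(enhancer = pid, gene = pairs$gene))
    absent <- !(links$gene %in% genes)
    if (any(absent)) {
      message(sum(absent),
              " enhancer-gene edge(s) dropped: gene absent from the network")
    }
    links <- links[!absent, ]
    used <- enhancers[enhancers$enhancer_id %in% links$enhancer, ]
    nodes <- bind_rows(nodes, tibble(
      name = used$enhancer_id, type = "enhancer", is_modifier = FALSE,
      class = used$class, chrom = used$chrom,
      start = as.integer(used$start), end = as.integer(used$end)
    ))
    edges <- bind_rows(edges, tibble(from = links$enhancer, to = links$gene,
                                     kind = "enhances"))
  }
  new_gren(nodes, edges)
}

new_gren <- function(nodes, edges) {
  stopifnot(!anyDuplicated(nodes$name),
            all(edges$from %in% nodes$name), all(edges$to %in% nodes$name))
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges)),
            class = "gren")
}

#' @export
print.gren <- function(x, ...) {
  cat("GREN:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "regulator"), "regulators,",
      sum(x$nodes$type == "target_gene"), "targets,",
      sum(x$nodes$type == "enhancer"), "enhancers ),",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Tidy a GREN
#' @param x A `gren` object.
#' @param ... Unused.
#' @return The node tibble.
#' @method tidy gren
#' @export
tidy.gren <- function(x, ...) x$nodes

#' One-row GREN summary
#' @param x A `gren` object.
#' @param ... Unused.
#' @return Tibble of node/edge counts by kind.
#' @method glance gren
#' @export
glance.gren <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_regulators = sum(x$nodes$type == "regulator"),
    n_targets = sum(x$nodes$type == "target_gene"),
    n_enhancers = sum(x$nodes$type == "enhancer"),
    n_modifiers = sum(x$nodes$is_modifier),
    n_edges = nrow(x$edges),
    n_enhancer_edges = sum(x$edges$kind == "enhances")
  )
}

#' Convert a GREN to an igraph graph
#' @param g A `gren` object.
#' @return An igraph graph with node/edge attributes; regulator edges are
#'   directed, enhancer-gene links carry `kind = "enhances"`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "gren"))
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = g$nodes)
}

#' Write a GREN as node and edge TSVs
#' @param g A `gren` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_gren <- function(g, dir) {
  stopifnot(inherits(g, "gren"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(g$nodes, file.path(dir, "nodes.tsv"), progress = FALSE)
  readr::write_tsv(g$edges, file.path(dir, "edges.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a GREN written by [write_gren()]
#' @param dir Directory with `nodes.tsv` and `edges.tsv`.
#' @return A `gren` object.
#' @export
read_gren <- function(dir) {
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"),
                           col_types = "cclccii", progress = FALSE)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           col_types = "ccc", progress = FALSE)
  new_gren(nodes, edges)
}

#' Extract the disease-specific subnetwork
#'
#' Induced subgraph on the core transcription factors, their deregulated
#' targets, the selected chromatin modifiers, and the enhancers linked to any
#' retained gene. Enhancers left without a gene edge are removed; core TFs
#' without deregulated targets are retained as isolated nodes.
#'
#' @param g A `gren` object.
#' @param core_tfs Character vector of core TF names (non-regulators are
#'   skipped with a warning).
#' @param deregulated_genes Genes selected by [select_deregulated_genes()].
#' @param selected_modifiers Chromatin-modifier genes to retain.
#' @return A `gren` object (subset of `g`).
#' @export
extract_disease_subnetwork <- function(g, core_tfs,
                                       deregulated_genes = character(),
                                       selected_modifiers = character()) {
  stopifnot(inherits(g, "gren"))
  regs <- g$nodes$name[g$nodes$type == "regulator"]
  unknown <- setdiff(core_tfs, regs)
  if (length(unknown) > 0) {
    warning("core TF(s) not regulator nodes, skipped: ",
            paste(unknown, collapse = ", "))
  }
  core <- intersect(core_tfs, regs)
  core_targets <- g$edges |>
    filter(.data$kind == "regulates", .data$from %in% core,
           .data$to %in% deregulated_genes) |>
    pull(.data$to)
  mods <- intersect(selected_modifiers,
                    g$nodes$name[g$nodes$is_modifier])
  keep_genes <- unique(c(core, core_targets, mods))
  enh_keep <- g$edges |>
    filter(.data$kind == "enhances", .data$to %in% keep_genes) |>
    pull(.data$from) |>
    unique()
  keep <- c(keep_genes, enh_keep)
  nodes <- g$nodes[g$nodes$name %in% keep, ]
  edges <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ]
  new_gren(nodes, edges)
}
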