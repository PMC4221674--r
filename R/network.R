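#' Build a three-layer plastic regulatory network
#'
#' Inner layer: phenotypically plastic miRNAs. Middle layer: genes that
#' are both predicted targets of those miRNAs and themselves
#' differentially expressed in the chosen contrast ("only miRNAs and
#' target genes that undergo altered transcriptional regulation are
#' included"). Outer layer: interaction partners of the target genes,
#' kept only when they interact with more than one distinct miRNA target
#' (`min_partner_links = 2`). Interactions are treated as undirected and
#' self-loops are dropped; genes already in the target layer are never
#' demoted to partners. miRNAs with no surviving target edge are dropped.
#'
#' @param plastic_mirnas Character vector of plastic miRNA ids.
#' @param target_map data.frame `mirna`, `target` (predicted targets).
#' @param plastic_genes Character vector of differentially expressed gene
#'   ids.
#' @param interactions data.frame `gene_a`, `gene_b` of gene-gene
#'   interaction evidence.
#' @param min_partner_links Minimum number of distinct target-layer
#'   neighbours a partner needs (default 2; 1 disables the filter).
#' @return An object of class `plastic_network`: list with `mirnas`,
#'   `targets`, `partners` (character vectors), `edges_mt` and `edges_tp`
#'   (data.frames `from`, `to`), and an empty `annotations` table to be
#'   filled by [overlay_histone_marks()].
#' @export
build_network <- function(plastic_mirnas, target_map, plastic_genes,
                          interactions, min_partner_links = 2L) {
  stopifnot(!is.null(plastic_mirnas), !is.null(target_map),
            !is.null(plastic_genes))
  tm <- target_map[target_map$mirna %in% plastic_mirnas &
                     target_map$target %in% plastic_genes, , drop = FALSE]
  targets <- sort(unique(tm$target))
  edges_mt <- unique(data.frame(from = tm$mirna, to = tm$target,
                                stringsAsFactors = FALSE))
  edges_mt <- edges_mt[order(edges_mt$from, edges_mt$to), , drop = FALSE]
  rownames(edges_mt) <- NULL
  mirnas <- sort(unique(edges_mt$from))

  edges_tp <- data.frame(from = character(0), to = character(0),
                         stringsAsFactors = FALSE)
  partners <- character(0)
  if (!is.null(interactions) && nrow(interactions) > 0L &&
      length(targets) > 0L) {
    ia <- data.frame(a = c(interactions$gene_a, interactions$gene_b),
                     b = c(interactions$gene_b, interactions$gene_a),
                     stringsAsFactors = FALSE)
    ia <- ia[ia$a != ia$b & ia$b %in% targets & !(ia$a %in% targets), ,
             drop = FALSE]
    ia <- unique(ia)
    deg <- table(ia$a)
    partners <- sort(names(deg)[deg >= min_partner_links])
    ia <- ia[ia$a %in% partners, , drop = FALSE]
    edges_tp <- data.frame(from = ia$b, to = ia$a,
                           stringsAsFactors = FALSE)
    edges_tp <- unique(edges_tp[order(edges_tp$from, edges_tp$to), ,
                                drop = FALSE])
    rownames(edges_tp) <- NULL
  }
  structure(
    list(mirnas = mirnas, targets = targets, partners = partners,
         edges_mt = edges_mt, edges_tp = edges_tp,
         annotations = data.frame(node = character(0), mark = character(0),
                                  stringsAsFactors = FALSE)),
    class = "plastic_network"
  )
}

#' @export
print.plastic_network <- function(x, ...) {
  cat(sprintf(paste0("Plastic regulatory network: %d miRNAs -> %d targets",
                     " -> %d partners (%d + %d edges)\n"),
              length(x$mirnas), length(x$targets), length(x$partners),
              nrow(x$edges_mt), nrow(x$edges_tp)))
  if (nrow(x$annotations) > 0L) {
    cat(sprintf("  histone annotations on %d nodes\n",
                length(unique(x$annotations$node))))
  }
  invisible(x)
}

#' Overlay differential histone marks on a network
#'
#' A gene node (target or partner), or a miRNA whose precursor locus is
#' listed in the maps under the miRNA id, is annotated with a mark when at
#' least one differential peak for that mark is assigned to it. Nodes may
#' carry several marks. Gene ids in the maps that do not occur in the
#' network are ignored.
#'
#' @param network A [build_network()] result.
#' @param peak_genes Named list (one element per mark, e.g. `H3K4me1`) of
#'   [assign_genes()] data.frames.
#' @param differential_peaks Named list (same names) of differential peak
#'   id vectors for each mark.
#' @return The network with its `annotations` table filled
#'   (`node`, `mark`).
#' @export
overlay_histone_marks <- function(network, peak_genes, differential_peaks) {
  stopifnot(inherits(network, "plastic_network"))
  stopifnot(identical(sort(names(peak_genes)),
                      sort(names(differential_peaks))))
  nodes <- c(network$mirnas, network$targets, network$partners)
  ann <- lapply(names(peak_genes), function(mark) {
    pg <- peak_genes[[mark]]
    dg <- unique(pg$gene_id[pg$peak_id %in% differential_peaks[[mark]]])
    hit <- intersect(dg, nodes)
    if (length(hit) == 0L) return(NULL)
    data.frame(node = hit, mark = mark, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  if (is.null(ann)) {
    ann <- data.frame(node = character(0), mark = character(0),
                      stringsAsFactors = FALSE)
  } else {
    ann <- ann[order(ann$node, ann$mark), , drop = FALSE]
    rownames(ann) <- NULL
  }
  network$annotations <- ann
  network
}

network_nodes <- function(network) {
  data.frame(
    node = c(network$mirnas, network$targets, network$partners),
    layer = c(rep("mirna", length(network$mirnas)),
              rep("target", length(network$targets)),
              rep("partner", length(network$partners))),
    stringsAsFactors = FALSE
  )
}

network_edges <- function(network) {
  rbind(
    if (nrow(network$edges_mt) > 0L)
      cbind(network$edges_mt, type = "targets", stringsAsFactors = FALSE),
    if (nrow(network$edges_tp) > 0L)
      cbind(network$edges_tp, type = "interacts", stringsAsFactors = FALSE)
  )
}

#' Export a plastic network
#'
#' `tsv` writes `<path>.nodes.tsv` (node, layer, semicolon-joined marks)
#' and `<path>.edges.tsv` (from, to, type) and round-trips losslessly via
#' [import_network()]. `graphml` writes a single file through igraph,
#' also lossless. `sif` writes one typed edge per line
#' (`from targets|interacts to`), a lossy but Cytoscape-ready format.
#'
#' @param network A `plastic_network`.
#' @param path Output path (prefix for `tsv`).
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "plastic_network"))
  format <- match.arg(format)
  nodes <- network_nodes(network)
  edges <- network_edges(network)
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  marks <- vapply(nodes$node, function(nd) {
    m <- sort(network$annotations$mark[network$annotations$node == nd])
    paste(m, collapse = ";")
  }, character(1))
  if (format == "tsv") {
    nodes$marks <- unname(marks)
    fn <- paste0(path, c(".nodes.tsv", ".edges.tsv"))
    utils::write.table(nodes, fn[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(edges, fn[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(fn))
  }
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to)
    writeLines(lines, path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = cbind(nodes,
                                                      marks = unname(marks)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a plastic network written by [export_network()]
#'
#' @param path Path (prefix for `tsv`) used at export time.
#' @param format `"tsv"` or `"graphml"`.
#' @return A `plastic_network`.
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    nodes <- utils::read.table(paste0(path, ".nodes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = "character")
    edges <- utils::read.table(paste0(path, ".edges.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = "character")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(node = igraph::V(g)$name,
                        layer = igraph::V(g)$layer,
                        marks = if (is.null(igraph::V(g)$marks)) ""
                                else igraph::V(g)$marks,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        type = if (igraph::ecount(g) > 0L)
                                 igraph::E(g)$type else character(0),
                        stringsAsFactors = FALSE)
  }
  nodes$marks[is.na(nodes$marks)] <- ""
  ann_rows <- nodes[nzchar(nodes$marks), , drop = FALSE]
  ann <- if (nrow(ann_rows) == 0L) {
    data.frame(node = character(0), mark = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(ann_rows)), function(i) {
      data.frame(node = ann_rows$node[i],
                 mark = strsplit(ann_rows$marks[i], ";", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)
    }))
  }
  ann <- ann[order(ann$node, ann$mark), , drop = FALSE]
  rownames(ann) <- NULL
  em <- edges[edges$type == "targets", c("from", "to"), drop = FALSE]
  ep <- edges[edges$type == "interacts", c("from", "to"), drop = FALSE]
  ## graphml is undirected; restore the canonical orientation
  mir <- sort(nodes$node[nodes$layer == "mirna"])
  tgt <- sort(nodes$node[nodes$layer == "target"])
  ptn <- sort(nodes$node[nodes$layer == "partner"])
  fix_dir <- function(e, from_set) {
    swap <- !(e$from %in% from_set)
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
    e <- unique(e[order(e$from, e$to), , drop = FALSE])
    rownames(e) <- NULL
    e
  }
  structure(
    list(mirnas = mir, targets = tgt, partners = ptn,
         edges_mt = fix_dir(em, mir), edges_tp = fix_dir(ep, tgt),
         annotations = ann),
    class = "plastic_network"
  )
}
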