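# Graph serialization: GraphML, node-link JSON, TSV edge list.
# All three are lossless: read(write(g)) reproduces the graph exactly,
# including edge weights at full double precision (%.17g / digits = NA).

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

.fmt_dbl <- function(x) sprintf("%.17g", x)

#' Write a token graph to disk
#'
#' Formats: `"graphml"` (node and edge attributes declared with GraphML
#' keys), `"json"` (node-link JSON, the payload the serving API uses), and
#' `"tsv"` (edge list `i`/`j`/`weight` plus a companion `<path>.nodes.tsv`).
#' Node attributes emitted in every format: `node_index`, `token_id`,
#' `token_string`, `reference`, `start`, `end`; edge attribute: `weight`.
#'
#' @param graph A `token_graph`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"json"`, `"tsv"`.
#' @return `path`, invisibly.
#' @seealso [read_token_graph()]
#' @export
write_token_graph <- function(graph, path,
                              format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  switch(format,
         graphml = .write_graphml(graph, path),
         json = .write_nodelink(graph, path),
         tsv = .write_edge_tsv(graph, path))
  invisible(path)
}

#' Read a token graph written by [write_token_graph()]
#' @param path File path.
#' @param format One of `"graphml"`, `"json"`, `"tsv"`.
#' @return A `token_graph`.
#' @export
read_token_graph <- function(path, format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("graph file not found: ", path)
  switch(format,
         graphml = .read_graphml(path),
         json = .read_nodelink(path),
         tsv = .read_edge_tsv(path))
}

.write_graphml <- function(graph, path) {
  n <- graph$nodes
  e <- graph$edges
  keys <- c(
    '<key id="g_reference" for="graph" attr.name="reference" attr.type="string"/>',
    '<key id="v_node_index" for="node" attr.name="node_index" attr.type="long"/>',
    '<key id="v_token_id" for="node" attr.name="token_id" attr.type="long"/>',
    '<key id="v_token_string" for="node" attr.name="token_string" attr.type="string"/>',
    '<key id="v_reference" for="node" attr.name="reference" attr.type="string"/>',
    '<key id="v_start" for="node" attr.name="start" attr.type="long"/>',
    '<key id="v_end" for="node" attr.name="end" attr.type="long"/>',
    '<key id="e_weight" for="edge" attr.name="weight" attr.type="double"/>')
  node_xml <- if (nrow(n)) sprintf(
    paste0('  <node id="n%d"><data key="v_node_index">%d</data>',
           '<data key="v_token_id">%d</data>',
           '<data key="v_token_string">%s</data>',
           '<data key="v_reference">%s</data>',
           '<data key="v_start">%d</data>',
           '<data key="v_end">%d</data></node>'),
    n$node_index, n$node_index, n$token_id, .xml_escape(n$token_string),
    .xml_escape(n$reference), n$start, n$end) else character(0)
  edge_xml <- if (nrow(e)) sprintf(
    '  <edge source="n%d" target="n%d"><data key="e_weight">%s</data></edge>',
    e$i, e$j, .fmt_dbl(e$weight)) else character(0)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    '<graph edgedefault="undirected">',
    sprintf('  <data key="g_reference">%s</data>',
            .xml_escape(graph$reference)),
    node_xml, edge_xml,
    '</graph>', '</graphml>'), path)
}

.read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ref <- xml2::xml_text(xml2::xml_find_first(doc, "./graph/data[@key='g_reference']"))
  node_el <- xml2::xml_find_all(doc, "./graph/node")
  nd <- function(key) vapply(node_el, function(el)
    xml2::xml_text(xml2::xml_find_first(el, sprintf("./data[@key='%s']", key))),
    "")
  nodes <- if (length(node_el)) data.frame(
    node_index = as.integer(nd("v_node_index")),
    token_id = as.integer(nd("v_token_id")),
    token_string = nd("v_token_string"),
    reference = nd("v_reference"),
    start = as.integer(nd("v_start")),
    end = as.integer(nd("v_end")),
    stringsAsFactors = FALSE) else .empty_nodes()
  edge_el <- xml2::xml_find_all(doc, "./graph/edge")
  edges <- if (length(edge_el)) data.frame(
    i = as.integer(sub("^n", "", xml2::xml_attr(edge_el, "source"))),
    j = as.integer(sub("^n", "", xml2::xml_attr(edge_el, "target"))),
    weight = as.numeric(vapply(edge_el, function(el)
      xml2::xml_text(xml2::xml_find_first(el, "./data[@key='e_weight']")), ""))
  ) else .empty_edges()
  token_graph(ref, nodes, edges)
}

.nodelink_payload <- function(graph) {
  list(reference = graph$reference,
       directed = FALSE,
       nodes = graph$nodes,
       links = data.frame(source = graph$edges$i, target = graph$edges$j,
                          weight = graph$edges$weight))
}

.write_nodelink <- function(graph, path) {
  jsonlite::write_json(.nodelink_payload(graph), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = I(17))
}

.read_nodelink <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- if (length(x$nodes)) {
    x$nodes$node_index <- as.integer(x$nodes$node_index)
    x$nodes$token_id <- as.integer(x$nodes$token_id)
    x$nodes$start <- as.integer(x$nodes$start)
    x$nodes$end <- as.integer(x$nodes$end)
    x$nodes
  } else .empty_nodes()
  edges <- if (length(x$links)) {
    data.frame(i = as.integer(x$links$source), j = as.integer(x$links$target),
               weight = as.numeric(x$links$weight))
  } else .empty_edges()
  token_graph(x$reference, nodes, edges)
}

.write_edge_tsv <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reference=%s", graph$reference), con)
  writeLines("i\tj\tweight", con)
  if (nrow(graph$edges)) {
    writeLines(sprintf("%d\t%d\t%s", graph$edges$i, graph$edges$j,
                       .fmt_dbl(graph$edges$weight)), con)
  }
  n <- graph$nodes
  ncon <- file(paste0(path, ".nodes.tsv"), "w")
  writeLines("node_index\ttoken_id\ttoken_string\treference\tstart\tend", ncon)
  if (nrow(n)) {
    writeLines(sprintf("%d\t%d\t%s\t%s\t%d\t%d", n$node_index, n$token_id,
                       n$token_string, n$reference, n$start, n$end), ncon)
  }
  close(ncon)
}

.read_edge_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  ref <- sub("^# reference=", "", first)
  e <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         colClasses = c("integer", "integer", "numeric"))
  npath <- paste0(path, ".nodes.tsv")
  if (!file.exists(npath)) stop("companion node TSV not found: ", npath)
  n <- utils::read.table(npath, sep = "\t", header = TRUE,
                         colClasses = c("integer", "integer", "character",
                                        "character", "integer", "integer"),
                         stringsAsFactors = FALSE, quote = "")
  nodes <- if (nrow(n)) n else .empty_nodes()
  edges <- if (nrow(e)) {
    names(e) <- c("i", "j", "weight")
    e
  } else .empty_edges()
  token_graph(ref, nodes, edges)
}
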