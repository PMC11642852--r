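#' Genomic context for a clicked node
#'
#' Resolves a graph node to its surrounding genome segment: the node's
#' interval extended by `flank` nucleotides on each side (clamped to the
#' reference), the raw sequence of that window, and the intervals of
#' graph-adjacent nodes that intersect the window — the data an interactive
#' front end needs to highlight the clicked token and its neighbors in
#' sequence context.
#'
#' @param graph A `token_graph`.
#' @param genome A `genome_source` for the same assembly.
#' @param node_index Index of the clicked node.
#' @param flank Context width in nucleotides on each side (default 50).
#' @return A `context_view`: list with `node_index`, `segment`,
#'   `window_start`, `window_end`, `focal_interval` (start, end), and
#'   `neighbor_intervals` (data frame `node_index`, `start`, `end`, sorted by
#'   start).
#' @export
node_context <- function(graph, genome, node_index, flank = 50L) {
  stopifnot(flank >= 0)
  r <- match(node_index, graph$nodes$node_index)
  if (is.na(r)) stop("unknown node: ", node_index)
  node <- graph$nodes[r, ]
  L <- .ref_length(genome, node$reference)
  ws <- max(0L, node$start - as.integer(flank))
  we <- min(L, node$end + as.integer(flank))
  adj <- c(graph$edges$j[graph$edges$i == node_index],
           graph$edges$i[graph$edges$j == node_index])
  nb <- graph$nodes[graph$nodes$node_index %in% adj, , drop = FALSE]
  nb <- nb[nb$start < we & nb$end > ws, , drop = FALSE]
  nb <- nb[order(nb$start), c("node_index", "start", "end"), drop = FALSE]
  rownames(nb) <- NULL
  structure(list(
    node_index = node_index,
    segment = fetch_segment(genome, node$reference, ws, we),
    window_start = ws, window_end = we,
    focal_interval = c(start = node$start, end = node$end),
    neighbor_intervals = nb
  ), class = "context_view")
}

#' JSON API handler over a graph and genome
#'
#' Builds the request router backing [serve_graph()] as a pure function, so
#' the API surface is testable without opening a socket. Routes:
#' \describe{
#'   \item{`GET /graph`}{node-link JSON of the graph; `?theta=` re-filters
#'     edges server-side (edges only shrink, nodes unchanged).}
#'   \item{`GET /node/{index}/context`}{a `context_view` as JSON;
#'     `?flank=` sets the window (default 50).}
#'   \item{`GET /search`}{`?reference=R&position=P`: the node whose genomic
#'     interval contains position P.}
#' }
#'
#' @param graph A `token_graph`.
#' @param genome A `genome_source`.
#' @return `function(method, path, query)` returning
#'   `list(status = <integer>, body = <jsonlite-ready list>)`; 404 for
#'   unknown nodes/positions, 400 for malformed parameters.
#' @export
graph_api <- function(graph, genome) {
  function(method, path, query = list()) {
    err <- function(status, msg) list(status = status,
                                      body = list(error = msg))
    if (!identical(method, "GET")) return(err(400L, "only GET is supported"))
    num <- function(name, default = NULL) {
      v <- query[[name]]
      if (is.null(v)) return(default)
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v)) NA else v
    }
    if (path == "/graph") {
      theta <- num("theta", 0)
      if (is.na(theta) || theta < 0 || theta > 1) {
        return(err(400L, "theta must be a number in [0, 1]"))
      }
      return(list(status = 200L,
                  body = .nodelink_payload(refilter_graph(graph, theta))))
    }
    if (grepl("^/node/[0-9]+/context$", path)) {
      idx <- as.integer(sub("^/node/([0-9]+)/context$", "\\1", path))
      flank <- num("flank", 50)
      if (is.na(flank) || flank < 0) return(err(400L, "flank must be >= 0"))
      if (!idx %in% graph$nodes$node_index) {
        return(err(404L, sprintf("no node %d", idx)))
      }
      cv <- node_context(graph, genome, idx, as.integer(flank))
      return(list(status = 200L, body = list(
        node_index = cv$node_index, segment = cv$segment,
        window_start = cv$window_start, window_end = cv$window_end,
        focal_interval = as.list(cv$focal_interval),
        neighbor_intervals = cv$neighbor_intervals)))
    }
    if (path == "/search") {
      pos <- num("position")
      if (is.null(pos) || is.na(pos)) {
        return(err(400L, "position is required and must be a number"))
      }
      ref <- query[["reference"]]
      if (!is.null(ref) && !identical(ref, graph$reference)) {
        return(err(404L, sprintf("graph covers reference '%s'",
                                 graph$reference)))
      }
      hit <- graph$nodes[graph$nodes$start <= pos & graph$nodes$end > pos, ,
                         drop = FALSE]
      if (nrow(hit) == 0L) {
        return(err(404L, sprintf("no node covers position %d", as.integer(pos))))
      }
      h <- hit[1L, ]
      return(list(status = 200L, body = list(
        node_index = h$node_index, token_string = h$token_string,
        start = h$start, end = h$end)))
    }
    err(404L, sprintf("no route for %s", path))
  }
}

.parse_query <- function(qs) {
  if (is.na(qs) || qs == "") return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) < 2L) "" else
    utils::URLdecode(p[2L]))
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

.parse_request_line <- function(line) {
  f <- strsplit(line, " ", fixed = TRUE)[[1L]]
  if (length(f) < 2L) return(NULL)
  target <- f[2L]
  q <- regmatches(target, regexpr("\\?.*$", target))
  path <- sub("\\?.*$", "", target)
  list(method = f[1L], path = path,
       query = .parse_query(if (length(q)) sub("^\\?", "", q) else ""))
}

.http_response <- function(status, body) {
  json <- jsonlite::toJSON(body, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, null = "null")
  reason <- c("200" = "OK", "400" = "Bad Request",
              "404" = "Not Found")[as.character(status)]
  paste0("HTTP/1.1 ", status, " ", reason, "\r\n",
         "Content-Type: application/json\r\n",
         "Content-Length: ", nchar(json, type = "bytes"), "\r\n",
         "Connection: close\r\n\r\n", json)
}

#' Serve a graph over HTTP
#'
#' Minimal single-threaded HTTP/1.1 JSON server over a node-link graph file
#' and an indexed FASTA, exposing the routes of [graph_api()]. Intended for
#' local interactive exploration; one request per connection.
#'
#' @param graph_file Path to a node-link JSON graph
#'   (see [write_token_graph()]).
#' @param fasta Path to the FASTA file the graph was built from.
#' @param host Interface to bind (informational; binds all local interfaces).
#' @param port TCP port.
#' @param max_requests Stop after this many requests (default `Inf`; finite
#'   values are useful for scripted runs).
#' @return Number of requests served, invisibly.
#' @export
serve_graph <- function(graph_file, fasta, host = "127.0.0.1", port = 8040L,
                        max_requests = Inf) {
  graph <- read_token_graph(graph_file, "json")
  genome <- open_genome(fasta)
  handler <- graph_api(graph, genome)
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  message("serving ", graph_file, " on http://", host, ":", port)
  served <- 0
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    line <- readLines(con, n = 1L)
    if (length(line)) {
      req <- .parse_request_line(line)
      res <- if (is.null(req)) {
        list(status = 400L, body = list(error = "malformed request"))
      } else handler(req$method, req$path, req$query)
      writeChar(.http_response(res$status, res$body), con, eos = NULL)
    }
    close(con)
    served <- served + 1
  }
  invisible(served)
}
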